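#' @useDynLib pepspectra, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import rlang
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   left_join inner_join anti_join distinct count n bind_rows pull rename
#'   row_number desc across all_of any_of case_when full_join
#' @importFrom tibble tibble as_tibble
#' @importFrom stats sd setNames
#' @importFrom utils head
NULL

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parse and format Enzyme Commission labels
#'
#' EC labels are dotted strings of 3 or 4 positive integer components
#' (e.g. `"6.1.1"` or `"6.1.1.3"`). `ec_parse()` validates them,
#' `ec_level3()` truncates 4-level labels to their level-3 parent, the
#' aggregation level at which enzymatic spectra are reported.
#'
#' @param x character vector of EC labels.
#' @return `ec_parse()` returns its input (validated, invisibly usable);
#'   `ec_level3()` returns the level-3 prefix of each label.
#' @examples
#' ec_level3(c("6.1.1.3", "5.4.99"))
#' @export
ec_parse <- function(x) {
  parts <- strsplit(x, ".", fixed = TRUE)
  ok <- vapply(parts, function(p) {
    length(p) %in% c(3L, 4L) && all(grepl("^[0-9]+$", p)) &&
      all(as.integer(p) >= 1L)
  }, logical(1))
  if (any(!ok)) {
    abort(paste0(
      "invalid EC label(s): ",
      paste(unique(x[!ok]), collapse = ", "),
      " (need 3 or 4 dot-separated positive integers)"
    ))
  }
  x
}

#' @rdname ec_parse
#' @export
ec_level3 <- function(x) {
  ec_parse(x)
  vapply(strsplit(x, ".", fixed = TRUE),
         function(p) paste(p[1:3], collapse = "."), character(1))
}

taxon_ranks <- c("kingdom", "phylum", "class", "order")

validate_peptides <- function(peptide, where = "peptide") {
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", peptide)
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "%s %d ('%s') contains letters outside the 20 amino-acid alphabet",
      where, i, peptide[i]
    ))
  }
  invisible(peptide)
}

new_sp_dictionary <- function(df, provenance = "in-memory") {
  df <- as_tibble(df)
  class(df) <- unique(c("sp_dictionary", class(df)))
  attr(df, "provenance") <- provenance
  df
}

#' Create a Specific Peptide dictionary
#'
#' A Specific Peptide (SP) is a short amino-acid string (7 residues or more)
#' whose exact presence in a protein marks a specific Enzyme Commission (EC)
#' category. A taxon-specific peptide (TSP) additionally carries the taxon
#' (at a stated rank) it is diagnostic of. The dictionary is a tibble with
#' columns `peptide`, `ec`, `taxon_rank`, `taxon_name` (the last two `NA`
#' for plain SPs).
#'
#' @param peptide character vector of uppercase peptides over the standard
#'   20-letter alphabet; no stop (`*`) or ambiguity codes.
#' @param ec character vector of EC labels (3 or 4 levels).
#' @param taxon_rank,taxon_name optional taxon annotation; rank must be one
#'   of kingdom, phylum, class, order.
#' @param min_length minimum peptide length retained (default 7, the length
#'   below which exact matches cease to be reliable function markers).
#' @param provenance free-text origin recorded as an attribute.
#' @return an `sp_dictionary` tibble.
#' @examples
#' sp_dictionary(c("NSISISGYH", "ISISGYHMQEAG"), c("5.4.99.2", "5.4.99.2"))
#' @export
sp_dictionary <- function(peptide, ec, taxon_rank = NA_character_,
                          taxon_name = NA_character_, min_length = 7L,
                          provenance = "in-memory") {
  peptide <- toupper(as.character(peptide))
  validate_peptides(peptide)
  ec_parse(ec)
  rk <- taxon_rank[!is.na(taxon_rank)]
  if (length(rk) && !all(rk %in% taxon_ranks)) {
    abort(paste0("taxon_rank must be one of: ",
                 paste(taxon_ranks, collapse = ", ")))
  }
  df <- tibble(peptide = peptide, ec = as.character(ec),
               taxon_rank = as.character(taxon_rank),
               taxon_name = as.character(taxon_name)) |>
    filter(nchar(.data$peptide) >= min_length) |>
    distinct(.data$peptide, .data$ec, .keep_all = TRUE)
  new_sp_dictionary(df, provenance)
}

#' Read a Specific Peptide dictionary from TSV
#'
#' The file format is tab-separated with a header line and columns
#' `peptide`, `ec` and optionally `taxon_rank`, `taxon_name`. Peptides
#' shorter than `min_length` are dropped; malformed records raise an error
#' naming the offending line.
#'
#' @param path path to the TSV file.
#' @param min_length minimum retained peptide length (default 7).
#' @return an `sp_dictionary` tibble.
#' @export
read_sp_dictionary <- function(path, min_length = 7L) {
  if (!file.exists(path)) abort(paste0("dictionary file not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("peptide", "ec") %in% names(df))) {
    abort("dictionary TSV must have 'peptide' and 'ec' columns")
  }
  bad_pep <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", toupper(df$peptide))
  if (any(bad_pep)) {
    abort(sprintf(
      "invalid peptide at line %d of %s: '%s'",
      which(bad_pep)[1] + 1L, path, df$peptide[which(bad_pep)[1]]
    ))
  }
  bad_ec <- !grepl("^[0-9]+(\\.[0-9]+){2,3}$", df$ec)
  if (any(bad_ec)) {
    abort(sprintf("invalid EC label at line %d of %s: '%s'",
                  which(bad_ec)[1] + 1L, path, df$ec[which(bad_ec)[1]]))
  }
  sp_dictionary(
    df$peptide, df$ec,
    taxon_rank = if ("taxon_rank" %in% names(df)) df$taxon_rank else NA_character_,
    taxon_name = if ("taxon_name" %in% names(df)) df$taxon_name else NA_character_,
    min_length = min_length, provenance = path
  )
}

#' Write a Specific Peptide dictionary to TSV
#'
#' @param dict an `sp_dictionary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sp_dictionary <- function(dict, path) {
  readr::write_tsv(as_tibble(dict), path, progress = FALSE)
  invisible(path)
}

#' Remove redundant Specific Peptides
#'
#' Discards every SP that contains, as a substring, a shorter dictionary
#' member with the same EC label: the longer peptide can never match without
#' the shorter one matching too, so it adds no information. Equal-length
#' duplicates with different EC labels are retained. Idempotent.
#'
#' @param dict an `sp_dictionary`.
#' @return the filtered `sp_dictionary`.
#' @examples
#' d <- sp_dictionary(c("ABCDEFG", "XABCDEFGY"), c("1.1.1", "1.1.1"))
#' filter_redundant(d)
#' @export
filter_redundant <- function(dict) {
  df <- as_tibble(dict)
  if (nrow(df) < 2) return(dict)
  keep <- rep(TRUE, nrow(df))
  for (e in unique(df$ec)) {
    idx <- which(df$ec == e)
    if (length(idx) < 2) next
    peps <- df$peptide[idx]
    ord <- order(nchar(peps))
    for (j in seq_along(ord)[-1]) {
      longer <- peps[ord[j]]
      shorter <- peps[ord[seq_len(j - 1)]]
      shorter <- shorter[nchar(shorter) < nchar(longer)]
      if (length(shorter) &&
          any(stringr::str_detect(longer, stringr::fixed(shorter)))) {
        keep[idx[ord[j]]] <- FALSE
      }
    }
  }
  new_sp_dictionary(df[keep, ], attr(dict, "provenance"))
}

#' Subset a dictionary to taxon-specific peptides of given ranks
#'
#' @param dict an `sp_dictionary` whose peptides carry taxon labels.
#' @param ranks character vector of ranks to retain (subset of kingdom,
#'   phylum, class, order). An empty vector yields an empty dictionary.
#' @return the filtered `sp_dictionary`.
#' @export
filter_taxon_rank <- function(dict, ranks) {
  df <- as_tibble(dict)
  if (nrow(df) && all(is.na(df$taxon_rank))) {
    abort("dictionary carries no taxon labels; cannot subset by rank")
  }
  bad <- setdiff(ranks, taxon_ranks)
  if (length(bad)) {
    abort(paste0("unknown rank(s): ", paste(bad, collapse = ", ")))
  }
  new_sp_dictionary(df[df$taxon_rank %in% ranks, ],
                    attr(dict, "provenance"))
}

#' @export
print.sp_dictionary <- function(x, ...) {
  cat(sprintf("<sp_dictionary> %d peptides (%d EC categories%s) [%s]\n",
              nrow(x), length(unique(x$ec)),
              if (any(!is.na(x$taxon_name)))
                sprintf(", %d taxon-labelled", sum(!is.na(x$taxon_name)))
              else "",
              attr(x, "provenance") %||% "?"))
  NextMethod()
  invisible(x)
}
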