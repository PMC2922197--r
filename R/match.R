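#' Build a multi-pattern exact matcher for a Specific Peptide dictionary
#'
#' Compiles the dictionary into an Aho-Corasick automaton (failure-link
#' trie), so that one pass over a query string reports every occurrence of
#' every dictionary peptide, overlapping occurrences included. Search cost
#' is linear in the total query length plus the number of hits, independent
#' of dictionary size.
#'
#' @param dict an `sp_dictionary` with at least one peptide.
#' @return an `sp_matcher` object holding the compiled automaton and the
#'   dictionary it was built from.
#' @export
sp_matcher <- function(dict) {
  df <- as_tibble(dict)
  if (nrow(df) == 0) abort("cannot build a matcher from an empty dictionary")
  handle <- .ac_build(df$peptide)
  structure(list(handle = handle, dict = df), class = "sp_matcher")
}

#' @export
print.sp_matcher <- function(x, ...) {
  cat(sprintf("<sp_matcher> automaton over %d peptides\n", nrow(x$dict)))
  invisible(x)
}

#' Locate dictionary peptides in query strings
#'
#' Low-level interface to the automaton: reports every (query, peptide,
#' offset) occurrence. Offsets are 0-based starts within the query.
#'
#' @param queries character vector of amino-acid strings (may contain `*`
#'   and `X`, which match nothing).
#' @param matcher an [sp_matcher()].
#' @return a tibble with columns `query` (index into `queries`), `peptide`,
#'   `ec`, `taxon_rank`, `taxon_name`, `offset_aa`.
#' @export
find_sp_hits <- function(queries, matcher) {
  stopifnot(inherits(matcher, "sp_matcher"))
  raw <- .ac_scan(matcher$handle, as.character(queries))
  d <- matcher$dict
  tibble(
    query = raw$subject,
    peptide = d$peptide[raw$pattern],
    ec = d$ec[raw$pattern],
    taxon_rank = d$taxon_rank[raw$pattern],
    taxon_name = d$taxon_name[raw$pattern],
    offset_aa = raw$start - 1L
  )
}

#' Scan short reads for Specific Peptide hits
#'
#' Translates every read into its six pseudo-peptides and records each
#' occurrence of each dictionary peptide that lies entirely within one of
#' them. Every occurrence counts: the same SP in two frames, or twice in
#' one frame, yields two hits — counts are occurrence counts, not read
#' counts.
#'
#' @param reads reads as accepted by [six_frame_translate()].
#' @param dict an `sp_dictionary`, or a prebuilt [sp_matcher()].
#' @param warn_length passed to [six_frame_translate()].
#' @return an `sp_hits` tibble with columns `read_id`, `peptide`, `ec`,
#'   `ec3` (level-3 EC), `taxon_rank`, `taxon_name`, `strand`, `frame`,
#'   `offset_aa`. Attributes `n_reads` and `read_length` (min/mean/max nt)
#'   describe the scanned read set.
#' @examples
#' d <- sp_dictionary("MAAHMAAW", "1.1.1")
#' scan_reads(c(r1 = "ATGGCAGCTCACATGGCAGCTTGG"), d, warn_length = FALSE)
#' @export
scan_reads <- function(reads, dict, warn_length = TRUE) {
  reads <- as_read_tbl(reads)
  matcher <- if (inherits(dict, "sp_matcher")) dict else sp_matcher(dict)
  pp <- six_frame_translate(reads, warn_length = warn_length)
  hits <- find_sp_hits(pp$peptide, matcher)
  out <- tibble(
    read_id = pp$read_id[hits$query],
    peptide = hits$peptide,
    ec = hits$ec,
    ec3 = ec_level3(hits$ec),
    taxon_rank = hits$taxon_rank,
    taxon_name = hits$taxon_name,
    strand = pp$strand[hits$query],
    frame = pp$frame[hits$query],
    offset_aa = hits$offset_aa
  )
  k <- nchar(reads$sequence)
  structure(out,
            class = c("sp_hits", class(out)),
            n_reads = nrow(reads),
            read_length = c(min = if (length(k)) min(k) else NA_real_,
                            mean = if (length(k)) mean(k) else NA_real_,
                            max = if (length(k)) max(k) else NA_real_,
                            sd = if (length(k) > 1) stats::sd(k) else 0))
}

#' Aggregate Specific Peptide hits into a category count table
#'
#' Tallies hits per category: the level-3 EC prefix for enzymatic spectra
#' (level-4-labelled SPs contribute to their level-3 parent), or the taxon
#' name for taxon-specific dictionaries. `count = "occurrences"` (default)
#' counts every occurrence; `count = "reads"` counts each read at most once
#' per category — the single switch between the two tallying policies.
#'
#' @param hits an `sp_hits` tibble from [scan_reads()].
#' @param by `"ec"` (level-3 EC categories) or `"taxon"` (taxon names).
#' @param count `"occurrences"` or `"reads"`.
#' @return a `hit_table` tibble with columns `category`, `n_hits`, `n_sps`
#'   (distinct supporting SP sequences), carrying forward the `n_reads` and
#'   `read_length` attributes.
#' @export
hit_table <- function(hits, by = c("ec", "taxon"),
                      count = c("occurrences", "reads")) {
  by <- arg_match(by)
  count <- arg_match(count)
  df <- as_tibble(hits)
  if (by == "taxon") {
    df <- df[!is.na(df$taxon_name), ]
    df$category <- df$taxon_name
  } else {
    df$category <- df$ec3
  }
  if (count == "reads") {
    df <- distinct(df, .data$read_id, .data$category, .keep_all = TRUE)
  }
  out <- df |>
    group_by(.data$category) |>
    summarise(n_hits = n(),
              n_sps = length(unique(.data$peptide)),
              .groups = "drop") |>
    arrange(desc(.data$n_hits))
  structure(out,
            class = c("hit_table", class(out)),
            by = by,
            n_reads = attr(hits, "n_reads"),
            read_length = attr(hits, "read_length"))
}

#' Flag anomalously dominated categories
#'
#' A quality-control heuristic for metagenomic read sets: a category whose
#' hit count exceeds the next-largest category by more than `fold` (default
#' 10, an order of magnitude) while being supported by at most `max_sps`
#' distinct SP sequences is likely an artifact (e.g. a contaminating
#' template sequenced many times) rather than genuine signal, and is
#' reported for re-examination.
#'
#' @param hits a `hit_table`, or an `sp_hits` tibble (aggregated at EC
#'   level 3 if so).
#' @param fold dominance threshold relative to the next-largest category.
#' @param max_sps maximum number of distinct supporting SPs for a flag.
#' @return a tibble with columns `category`, `n_hits`, `n_sps`,
#'   `next_largest`, `fold`; zero rows when nothing is anomalous (a table
#'   with fewer than two categories has no comparator and is never flagged).
#' @export
flag_anomalies <- function(hits, fold = 10, max_sps = 2L) {
  tab <- if (is.data.frame(hits) &&
             all(c("category", "n_hits", "n_sps") %in% names(hits))) {
    hits
  } else {
    hit_table(hits)
  }
  df <- as_tibble(tab)
  empty <- tibble(category = character(), n_hits = integer(),
                  n_sps = integer(), next_largest = integer(),
                  fold = double())
  if (nrow(df) < 2) return(empty)
  df <- arrange(df, desc(.data$n_hits))
  next_largest <- vapply(seq_len(nrow(df)), function(i) {
    max(df$n_hits[-i])
  }, numeric(1))
  flagged <- df$n_hits > fold * next_largest & df$n_sps <= max_sps
  if (!any(flagged)) return(empty)
  tibble(
    category = df$category[flagged],
    n_hits = df$n_hits[flagged],
    n_sps = df$n_sps[flagged],
    next_largest = as.integer(next_largest[flagged]),
    fold = df$n_hits[flagged] / next_largest[flagged]
  )
}

#' Write hit streams and hit tables
#'
#' TSV writers mirroring the hit-extraction web-service output: one row per
#' SP occurrence (`write_hits`) or per category (`write_hit_table`;
#' `write_hit_table_json` adds the read-set summary).
#'
#' @param hits an `sp_hits` tibble.
#' @param tab a `hit_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  readr::write_tsv(as_tibble(hits), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
write_hit_table <- function(tab, path) {
  readr::write_tsv(as_tibble(tab), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
write_hit_table_json <- function(tab, path) {
  jsonlite::write_json(
    list(
      by = attr(tab, "by"),
      n_reads = attr(tab, "n_reads"),
      read_length = as.list(attr(tab, "read_length")),
      counts = as_tibble(tab)
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
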