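#' Percentage of multiple-copy species entries for an aaRS category
#'
#' Aminoacyl-tRNA synthetases are mostly single-copy per bacterial species;
#' a category's suitability as a single-copy marker is measured by the
#' fraction of its protein entries that are extra copies:
#' `100 * (doublets + 2 * triplets) / proteins`, where a doublet (triplet)
#' is a species with 2 (3) entries — each contributing 1 (2) surplus
#' proteins.
#'
#' @param doublets,triplets,proteins integer vectors: species with 2
#'   entries, species with 3 entries, and total protein entries.
#' @return percentage(s), vectorised.
#' @examples
#' percent_multiples(68, 1, 172)  # 40.70 (a poor single-copy marker)
#' @export
percent_multiples <- function(doublets, triplets, proteins) {
  if (any(proteins <= 0)) abort("proteins must be positive")
  if (any(doublets * 2 + triplets * 3 > proteins)) {
    abort("doublets and triplets imply more proteins than reported")
  }
  100 * (doublets + 2 * triplets) / proteins
}

#' Select the S61 set of single-copy aaRS categories
#'
#' Keeps the level-4 aaRS categories (6.1.1.x) whose percentage of multiple
#' entries, rounded to one decimal, is at most `threshold_percent`
#' (default 2). These near-single-copy categories — the "S61" set — are
#' the ones whose taxon-specific peptides support quantitative taxonomic
#' mixtures, since one hit-corrected enzyme then corresponds to one
#' genome.
#'
#' @param multiplicity a tibble with columns `ec`, `doublets`, `triplets`,
#'   `proteins` (see [aars_multiplicity()] for the packaged reference
#'   statistics).
#' @param threshold_percent inclusion threshold on the rounded percentage.
#' @return character vector of selected EC labels.
#' @export
select_s61 <- function(multiplicity, threshold_percent = 2) {
  if (threshold_percent < 0) abort("threshold must be non-negative")
  df <- as_tibble(multiplicity)
  pm <- percent_multiples(df$doublets, df$triplets, df$proteins)
  df$ec[round(pm, 1) <= threshold_percent]
}

#' Classification precision
#'
#' `100 * TP / (TP + FP)`: of the enzymes predicted for taxa, the
#' percentage assigned to the correct one.
#'
#' @param tp,fp true- and false-positive signal (predicted enzyme numbers).
#' @return precision in percent.
#' @export
precision <- function(tp, fp) {
  if (any(tp + fp <= 0)) abort("precision undefined: tp + fp must be > 0")
  100 * tp / (tp + fp)
}

#' Predict a taxonomic mixture from taxon-specific peptide hits
#'
#' Divides each taxon's TSP hit count by its raw factor (expected hits per
#' enzyme), giving predicted numbers of marker enzymes that are
#' proportional to numbers of cells. Taxa whose (unrounded) prediction is
#' below `no_call_threshold` are moved to the no-call set rather than
#' reported; taxa with hits but no factor row are reported as
#' `"no prediction"` (some taxa simply have no TSPs). Percentages are
#' computed among called taxa only. Kingdom-, phylum- and class-level
#' classifications are independent runs: a TSP is specific to exactly one
#' taxon at its own rank.
#'
#' Factors derived from curated proteomes tend to overestimate hit density
#' in novel organisms, so absolute predictions are lower-bound estimates.
#'
#' @param hits a `hit_table` keyed by taxon (from
#'   `hit_table(hits, by = "taxon")`), or any tibble with `category`,
#'   `n_hits` where `category` is the taxon name.
#' @param factors a tibble with columns `taxon` and `factor` (see
#'   [s61_taxon_factors()]), optionally `parent` and `rank`.
#' @param level taxonomic rank reported (`"kingdom"`, `"phylum"`,
#'   `"class"`); requires a `rank` column in `factors` and, for scanned
#'   hits, taxon ranks in the dictionary. Use `NULL` (default) to treat all
#'   rows of `hits` as one level.
#' @param no_call_threshold minimum predicted enzymes for a call
#'   (default 1).
#' @return a `taxon_mixture` tibble with columns `taxon`, `n_hits`,
#'   `factor`, `predicted`, `percent_among_called`, `status`
#'   (`"called"`, `"no_call"`, `"no prediction"`).
#' @examples
#' hits <- tibble::tibble(category = "Bacteria", n_hits = 1271)
#' predict_taxon_mixture(hits, s61_taxon_factors())
#' @export
predict_taxon_mixture <- function(hits, factors, level = NULL,
                                  no_call_threshold = 1) {
  ht <- as_tibble(hits)[, c("category", "n_hits")]
  names(ht)[1] <- "taxon"
  ft <- as_tibble(factors)
  if (!all(c("taxon", "factor") %in% names(ft))) {
    abort("taxon factor table needs 'taxon' and 'factor' columns")
  }
  if (!is.null(level)) {
    if (!"rank" %in% names(ft)) {
      abort("level-specific prediction needs a 'rank' column in factors")
    }
    ft <- ft[ft$rank == level, ]
    ht <- ht[ht$taxon %in% ft$taxon | !ht$taxon %in% factors$taxon, ]
  }
  df <- dplyr::left_join(ht, ft[, intersect(c("taxon", "factor", "parent"),
                                            names(ft))],
                         by = "taxon")
  df$predicted <- df$n_hits / df$factor
  df$status <- dplyr::case_when(
    is.na(df$factor) ~ "no prediction",
    df$predicted < no_call_threshold ~ "no_call",
    TRUE ~ "called"
  )
  called_total <- sum(df$predicted[df$status == "called"])
  df$percent_among_called <- ifelse(
    df$status == "called" & called_total > 0,
    100 * df$predicted / called_total,
    NA_real_
  )
  out <- df |>
    select(any_of(c("taxon", "n_hits", "factor", "predicted",
                    "percent_among_called", "status"))) |>
    arrange(desc(.data$status == "called"), desc(.data$predicted))
  structure(out,
            class = c("taxon_mixture", class(out)),
            level = level %||% "all",
            no_call_threshold = no_call_threshold)
}

#' @export
print.taxon_mixture <- function(x, ...) {
  cat(sprintf(
    "<taxon_mixture> level %s (%d called, %d no-call; lower-bound estimates)\n",
    attr(x, "level"), sum(x$status == "called"), sum(x$status == "no_call")
  ))
  NextMethod()
  invisible(x)
}

#' Write a taxon mixture report
#'
#' @param mixture a `taxon_mixture`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxon_mixture <- function(mixture, path) {
  df <- as_tibble(mixture)
  df$level <- attr(mixture, "level")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_taxon_mixture
#' @export
write_taxon_mixture_json <- function(mixture, path) {
  jsonlite::write_json(
    list(
      level = attr(mixture, "level"),
      no_call_threshold = attr(mixture, "no_call_threshold"),
      note = "factors are trained on curated proteomes; treat absolute predictions as lower bounds",
      mixture = as_tibble(mixture)
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "pepspectra")
  if (path == "") abort(paste0("packaged data file missing: ", file))
  path
}

#' Packaged multiplicity statistics of bacterial aaRS categories
#'
#' Reference counts, per level-4 aaRS category (6.1.1.x), of species with
#' double and triple entries among curated Swiss-Prot bacterial proteins,
#' together with the published percent-multiples value and S61 membership
#' flag. Input to [select_s61()].
#'
#' @return a tibble with columns `ec`, `doublets`, `triplets`, `proteins`,
#'   `percent_multiples`, `s61`.
#' @export
aars_multiplicity <- function() {
  readr::read_tsv(extdata("aars_multiplicity.tsv"),
                  col_types = "ciiidl", progress = FALSE)
}

#' Packaged raw factors for S61 taxon-specific peptides
#'
#' Reference calibration of the S61 TSP set against curated Swiss-Prot
#' proteomes: per taxon, the number of marker enzymes, TSPs, TSP hits, and
#' the raw factor `n_hits / n_enzymes` used by
#' [predict_taxon_mixture()]. Factors correspond to effectively unlimited
#' read length; for short reads only their ratios should be trusted, and
#' absolute predictions are lower bounds.
#'
#' @return a tibble with columns `rank`, `parent`, `taxon`, `n_enzymes`,
#'   `n_tsps`, `n_hits`, `factor`.
#' @export
s61_taxon_factors <- function() {
  readr::read_tsv(extdata("s61_taxon_factors.tsv"),
                  col_types = "ccciiid", progress = FALSE)
}

#' Packaged normalised EC factors for 50-nt reads
#'
#' Reference normalised factors (and their standard deviations over
#' super-organism combinations) for the leading level-3 EC categories,
#' derived from 50-nt reads of annotated bacterial genomes at 5x coverage.
#' The reference category 6.1.1 has factor 1 and SD 0 by construction.
#'
#' @return a `factor_table` tibble with columns `category`, `nf`, `nf_sd`.
#' @export
reference_norm_factors <- function() {
  df <- readr::read_tsv(extdata("norm_factors_sr50.tsv"),
                        col_types = "cdd", progress = FALSE)
  new_factor_table(df, 50, "6.1.1")
}

#' Packaged demonstration SP dictionary
#'
#' A small dictionary shipped for examples and the command-line quick
#' start: the two published methylmalonyl-CoA mutase (EC 5.4.99.2) marker
#' peptides plus synthetic example peptides under real EC labels.
#'
#' @return an `sp_dictionary`.
#' @export
demo_dictionary <- function() {
  read_sp_dictionary(extdata("demo_dictionary.tsv"))
}
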