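#' Predict the enzymatic spectrum of a read set
#'
#' Converts SP hit counts into predicted numbers of enzyme genes per EC
#' category: `predicted = n_hits / (coverage * rf)`, with `rf` the raw
#' factor calibrated at (or close to) the reads' length. For real
#' metagenomes the coverage is unknown and left at 1, in which case
#' predictions are coverage-weighted gene counts — e.g. a predicted 60
#' aminoacyl-tRNA synthetases, at roughly 20 aaRS genes per bacterial
#' genome, reads as "of the order of three cells' worth of genomes"
#' (see [cells_estimate()]). The relative spectrum divides by the
#' reference category's prediction. Categories with hits but no calibrated
#' factor are retained with `predicted = NA` (flagged `uncalibrated`), not
#' silently dropped.
#'
#' When the scanned reads' lengths are heterogeneous (coefficient of
#' variation above 20%), a warning notes that single-read-length factors
#' are being applied to mixed lengths.
#'
#' @param hits a `hit_table` keyed by EC category.
#' @param factors a `factor_table` with an `rf` column (and optionally
#'   `rf_sd`, `nf`, `nf_sd`).
#' @param coverage known sequencing depth of the read set (default 1 =
#'   unknown; predictions then count genome equivalents).
#' @param reference reference category for the relative spectrum.
#' @return an `enzymatic_spectrum` tibble with columns `category`,
#'   `n_hits`, `rf_used`, `predicted`, `relative`, `uncalibrated`.
#' @export
predict_spectrum <- function(hits, factors, coverage = 1,
                             reference = attr(factors, "reference") %||% "6.1.1") {
  stopifnot(is.data.frame(hits), is.data.frame(factors))
  rl <- attr(hits, "read_length")
  if (!is.null(rl) && "sd" %in% names(rl) && is.finite(rl[["mean"]]) &&
      rl[["mean"]] > 0) {
    cv <- rl[["sd"]] / rl[["mean"]]
    if (!is.na(cv) && cv > 0.2) {
      warn(paste0(
        "read lengths are heterogeneous (CV ", round(100 * cv), "%); ",
        "factors for a single read length are being applied"
      ))
    }
  }
  ht <- as_tibble(hits)[, c("category", "n_hits")]
  ft <- as_tibble(factors)
  keep <- intersect(c("category", "rf", "rf_sd", "nf", "nf_sd"), names(ft))
  df <- dplyr::full_join(ht, ft[, keep], by = "category")
  df$n_hits[is.na(df$n_hits)] <- 0L
  df$rf_used <- df$rf
  df$predicted <- df$n_hits / (coverage * df$rf_used)
  df$uncalibrated <- is.na(df$rf_used) & df$n_hits > 0
  ref_pred <- df$predicted[df$category == reference]
  if (length(ref_pred) == 1 && !is.na(ref_pred) && ref_pred > 0) {
    df$relative <- df$predicted / ref_pred
  } else {
    warn(sprintf(
      "reference category %s absent from hits; relative spectrum unavailable",
      reference
    ))
    df$relative <- NA_real_
  }
  out <- df |>
    select("category", "n_hits", "rf_used", "predicted", "relative",
           "uncalibrated") |>
    arrange(.data$category)
  structure(out,
            class = c("enzymatic_spectrum", class(out)),
            reference = reference,
            coverage = coverage,
            read_length = attr(hits, "read_length"),
            factor_read_length = attr(factors, "read_length"))
}

#' Chi-square agreement between predicted and known spectra
#'
#' For categories with known gene numbers and calibration standard
#' deviations, computes the per-category terms `((predicted - known)/sd)^2`
#' and their mean, the chi-square per degree of freedom. A well-calibrated
#' prediction gives a value of order 1 (the statistic is expected to be of
#' the order of the number of degrees of freedom); single-organism
#' predictions from metagenome-trained factors typically give much larger
#' values, because metagenomic averaging smooths out between-organism
#' differences.
#'
#' @param predicted,known named numeric vectors (names = categories), or
#'   tibbles with `category` plus a value column.
#' @param sd named numeric vector of standard deviations on the compared
#'   scale; `sd = 0` is only admissible where `predicted == known` (term 0).
#' @return a `spectrum_fit` object (list with `chi2_per_dof`, `n_dof`,
#'   `terms` tibble); see [tidy.spectrum_fit()] and
#'   [glance.spectrum_fit()].
#' @export
chi_square_fit <- function(predicted, known, sd) {
  as_named <- function(x) {
    if (is.data.frame(x)) {
      val <- setdiff(names(x), "category")[1]
      setNames(x[[val]], x$category)
    } else x
  }
  predicted <- as_named(predicted)
  known <- as_named(known)
  sd <- as_named(sd)
  cats <- intersect(names(predicted), names(known))
  cats <- intersect(cats, names(sd))
  if (length(cats) == 0) abort("no common categories to compare")
  p <- predicted[cats]
  m <- known[cats]
  s <- sd[cats]
  zero_bad <- s == 0 & p != m
  if (any(zero_bad)) {
    abort(paste0("sd = 0 with predicted != known for: ",
                 paste(cats[zero_bad], collapse = ", ")))
  }
  term <- ifelse(s == 0, 0, ((p - m) / s)^2)
  structure(
    list(
      chi2_per_dof = mean(term),
      n_dof = length(cats),
      terms = tibble(category = cats, predicted = unname(p),
                     known = unname(m), sd = unname(s),
                     term = unname(term))
    ),
    class = "spectrum_fit"
  )
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("<spectrum_fit> chi-square/dof = %.3f over %d categories\n",
              x$chi2_per_dof, x$n_dof))
  invisible(x)
}

#' Broom-style accessors for spectrum fits
#'
#' `tidy()` returns the per-category terms; `glance()` the one-row summary.
#'
#' @param x a `spectrum_fit` from [chi_square_fit()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.spectrum_fit <- function(x, ...) x$terms

#' @rdname tidy.spectrum_fit
#' @export
glance.spectrum_fit <- function(x, ...) {
  tibble(chi2_per_dof = x$chi2_per_dof, n_dof = x$n_dof,
         chi2 = x$chi2_per_dof * x$n_dof)
}

#' Rough cell-count estimate from the aaRS prediction
#'
#' Aminoacyl-tRNA synthetases (EC 6.1.1) are essentially single-copy per
#' amino acid per bacterial genome (about 20 genes), which makes the
#' predicted 6.1.1 count a calibrating device: dividing it by
#' `aars_per_genome` estimates how many genome equivalents ("cells") the
#' read set covers.
#'
#' @param spectrum an `enzymatic_spectrum`.
#' @param aars_per_genome aaRS genes per genome (default 20).
#' @param reference the aaRS category key (default `"6.1.1"`).
#' @return scalar estimate of genome equivalents (0 when the category is
#'   absent).
#' @export
cells_estimate <- function(spectrum, aars_per_genome = 20,
                           reference = "6.1.1") {
  df <- as_tibble(spectrum)
  pred <- df$predicted[df$category == reference]
  if (length(pred) == 0 || is.na(pred)) return(0)
  pred / aars_per_genome
}

#' Write an enzymatic spectrum report
#'
#' @param spectrum an `enzymatic_spectrum`.
#' @param path output path (TSV or, for the JSON variant, JSON).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_tsv(as_tibble(spectrum), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
write_spectrum_json <- function(spectrum, path) {
  jsonlite::write_json(
    list(
      reference = attr(spectrum, "reference"),
      coverage = attr(spectrum, "coverage"),
      spectrum = as_tibble(spectrum)
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
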