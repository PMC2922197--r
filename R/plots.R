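#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an enzymatic spectrum
#'
#' Bar chart of predicted enzyme numbers (or the relative spectrum) per EC
#' category; uncalibrated categories are greyed out.
#'
#' @param object an `enzymatic_spectrum`.
#' @param relative plot the relative spectrum instead of absolute
#'   predictions.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.enzymatic_spectrum <- function(object, relative = FALSE, ...) {
  df <- as_tibble(object)
  df$value <- if (relative) df$relative else df$predicted
  df <- df[!is.na(df$value) | df$uncalibrated, ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$category, -.data$value),
    y = .data$value, fill = .data$uncalibrated
  )) +
    ggplot2::geom_col(show.legend = any(df$uncalibrated)) +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "#2b6cb0", `TRUE` = "grey70"),
      labels = c(`FALSE` = "calibrated", `TRUE` = "uncalibrated"),
      name = NULL
    ) +
    ggplot2::labs(
      x = "EC category (level 3)",
      y = if (relative) "relative to reference" else
        "predicted enzyme genes (x coverage)",
      title = "Enzymatic spectrum"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a factor table
#'
#' Normalised factors with standard-deviation error bars when present.
#'
#' @param object a `factor_table`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.factor_table <- function(object, ...) {
  df <- as_tibble(object)
  value <- if ("nf" %in% names(df)) "nf" else "rf"
  df$value <- df[[value]]
  df$sd <- if (paste0(value, "_sd") %in% names(df)) df[[paste0(value, "_sd")]] else NA_real_
  df <- df[!is.na(df$value), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$category, -.data$value), y = .data$value
  )) +
    ggplot2::geom_col(fill = "#2f855a") +
    ggplot2::labs(
      x = "EC category",
      y = if (value == "nf") "normalised factor" else "raw factor",
      title = sprintf("Calibration factors (read length %s)",
                      as.character(attr(object, "read_length")))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (any(!is.na(df$sd))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value - .data$sd,
                   ymax = .data$value + .data$sd),
      width = 0.3
    )
  }
  p
}

#' Plot a taxon mixture
#'
#' Percentages among called taxa; no-call taxa are annotated in the
#' subtitle.
#'
#' @param object a `taxon_mixture`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.taxon_mixture <- function(object, ...) {
  df <- as_tibble(object)
  called <- df[df$status == "called", ]
  nc <- df$taxon[df$status != "called"]
  ggplot2::ggplot(called, ggplot2::aes(
    x = stats::reorder(.data$taxon, -.data$percent_among_called),
    y = .data$percent_among_called
  )) +
    ggplot2::geom_col(fill = "#975a16") +
    ggplot2::labs(
      x = paste0("taxon (", attr(object, "level"), ")"),
      y = "% among called taxa",
      title = "Taxonomic mixture",
      subtitle = if (length(nc))
        paste0("no call / no prediction: ", paste(nc, collapse = ", "))
      else NULL
    ) +
    ggplot2::theme_minimal()
}
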