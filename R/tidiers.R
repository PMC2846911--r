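#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a classification result
#'
#' @param x A `u12_classification` from [classify_introns()].
#' @param ... Unused.
#' @return The per-intron tibble of scores, flags and categories.
#' @method tidy u12_classification
#' @export
tidy.u12_classification <- function(x, ...) {
  x$introns
}

#' One-row summary of a classification result
#'
#' @param x A `u12_classification`.
#' @param ... Unused.
#' @return A single-row tibble: intron count, per-category counts under the
#'   log-odds scheme, counts of B/S/R-flagged introns, and the z-score
#'   thresholds.
#' @method glance u12_classification
#' @export
glance.u12_classification <- function(x, ...) {
  counts <- x$summary |>
    dplyr::select("category", "sheth_n") |>
    tidyr::pivot_wider(names_from = "category", values_from = "sheth_n",
                       names_prefix = "n_")
  dplyr::bind_cols(
    tibble::tibble(
      n_introns = nrow(x$introns),
      n_burge = sum(x$introns$burge_flag, na.rm = TRUE),
      n_sheth = sum(x$introns$sheth_flag, na.rm = TRUE),
      n_rule = sum(x$introns$rule_flag, na.rm = TRUE),
      min_z5 = x$thresholds$min_z5,
      min_zb = x$thresholds$min_zb
    ),
    counts
  )
}

#' Score-space scatter plot of a classification result
#'
#' Plots each intron's branch z-score against its 5' splice-site z-score,
#' colored by category, with the reference-set rectangle (the inclusive
#' thresholds both scores must reach to qualify as U12) drawn in.
#'
#' @param object A `u12_classification`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot u12_classification
#' @export
autoplot.u12_classification <- function(object, ...) {
  df <- object$introns
  th <- object$thresholds
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z5, y = .data$zb,
                                   colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::annotate("rect",
      xmin = th$min_z5, xmax = Inf, ymin = th$min_zb, ymax = Inf,
      fill = NA, colour = "blue", linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "5' splice site z-score",
      y = "branch site z-score",
      colour = "category"
    ) +
    ggplot2::theme_minimal()
}

#' Intron length histogram
#'
#' @param introns Intron tibble with a `length` column.
#' @param binwidth Histogram bin width in nt (default 5).
#' @return A ggplot object.
#' @export
plot_intron_lengths <- function(introns, binwidth = 5) {
  ggplot2::ggplot(introns, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::labs(x = "intron length (nt)", y = "count") +
    ggplot2::theme_minimal()
}
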