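#' Plot landscape versus exploited-fraction summaries over time
#'
#' Given a tibble of stacked [exploited_vs_landscape()] results (rows for
#' several periods), draws the classic two-band comparison: per-period
#' medians with midspread ribbons and darker bootstrap-CI ribbons, one
#' colour per source (landscape vs exploited fraction), faceted by crop
#' label when several are present.
#'
#' @param comparisons A tibble combining `tidy()`d period comparisons;
#'   must carry `period`, `source`, `median`, `q1`, `q3`, `ci_low`,
#'   `ci_high` and optionally `crop_label`. `period` is taken as ordered.
#' @return A ggplot object.
#' @export
plot_period_comparison <- function(comparisons) {
  stopifnot(all(c("period", "source", "median", "q1", "q3") %in%
                  names(comparisons)))
  comparisons$period <- factor(comparisons$period,
                               levels = unique(comparisons$period))
  p <- ggplot2::ggplot(comparisons,
                       ggplot2::aes(x = .data$period, group = .data$source,
                                    colour = .data$source, fill = .data$source)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.4, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median)) +
    ggplot2::labs(x = NULL, y = "PAgP (tFM/ha)", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("crop_label" %in% names(comparisons) &&
      length(unique(comparisons$crop_label)) > 1) {
    p <- p + ggplot2::facet_grid(rows = ggplot2::vars(.data$crop_label),
                                 scales = "free_y")
  }
  p
}

#' Plot a centennial difference series
#'
#' Step plot of the exploited-minus-landscape median difference through
#' time (years BP decreasing left to right), with the zero line marked.
#'
#' @param series Output of [difference_series()].
#' @return A ggplot object.
#' @export
plot_difference_series <- function(series) {
  stopifnot(all(c("century_bp", "difference") %in% names(series)))
  ggplot2::ggplot(series, ggplot2::aes(x = .data$century_bp,
                                       y = .data$difference)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_step() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "years BP", y = "exploited - landscape median (tFM/ha)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_period_comparison
#' @param object A `period_comparison`.
#' @param ... Unused.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.period_comparison <- function(object, ...) {
  plot_period_comparison(tidy(object))
}

#' Plot a binned intensity regression
#'
#' Bin-level settlement intensity against yield-bin midpoint (point size
#' proportional to landscape bin area) with the fitted least-squares
#' line.
#'
#' @param object An `intensity_regression`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.intensity_regression <- function(object, ...) {
  b <- object$bins
  p <- ggplot2::ggplot(b, ggplot2::aes(x = .data$bin_mid, y = .data$intensity)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$area_km2), alpha = 0.7) +
    ggplot2::labs(x = "PAgP bin midpoint (tFM/ha)",
                  y = expression("site intensity (sites/km"^2 * ")"),
                  size = expression("bin area (km"^2 * ")"),
                  title = sprintf("%s / %s", object$period, object$crop_label)) +
    ggplot2::theme_minimal()
  if (object$defined) {
    p <- p + ggplot2::geom_abline(slope = object$slope,
                                  intercept = object$intercept,
                                  colour = "firebrick")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
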