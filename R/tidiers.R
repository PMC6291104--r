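#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an intensity regression
#'
#' `tidy()` returns the per-bin table (one row per nonempty yield bin);
#' `glance()` returns the one-row fit summary.
#'
#' @param x An `intensity_regression`.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.intensity_regression <- function(x, ...) {
  dplyr::mutate(x$bins, period = x$period, crop_label = x$crop_label,
                .before = 1)
}

#' @rdname tidy.intensity_regression
#' @export
#' @exportS3Method generics::glance
glance.intensity_regression <- function(x, ...) {
  tibble::tibble(
    period = x$period, crop_label = x$crop_label,
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    weighted = x$weighted, defined = x$defined,
    n_bins = nrow(x$bins), n_sites = x$n_sites
  )
}

#' Tidy a period comparison
#'
#' Returns the comparison rows as a plain tibble with the median
#' difference attached as a column.
#'
#' @param x A `period_comparison` (see [exploited_vs_landscape()]).
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.period_comparison <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$median_difference <- attr(x, "median_difference")
  out
}
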