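#' Generate a centennial climate series with step events
#'
#' Produces centennial-step annual-mean temperature and precipitation for
#' a span of years BP: baseline + linear trend + first-order
#' autocorrelated noise, with superimposed step "events" that multiply
#' precipitation and/or shift temperature over a bounded window (the
#' canonical case being a multiplicative precipitation drop over
#' 4200-4000 BP). Events apply to every century `c` with
#' `start_bp >= c >= end_bp`, inclusive. Precipitation driven negative is
#' clipped to zero with a warning.
#'
#' @param seed Integer RNG seed.
#' @param start_bp,end_bp Span bounds in years BP (start older).
#' @param baseline_t Baseline annual-mean temperature, degrees C.
#' @param baseline_p Baseline annual precipitation, mm/yr.
#' @param trend_t,trend_p Linear drift per 1000 years (applied forward in
#'   time from `start_bp`).
#' @param events A data frame with columns `start_bp`, `end_bp` and either
#'   or both of `precip_multiplier`, `temp_shift`; `NULL` for none.
#' @param noise_sd_t,noise_sd_p Marginal noise standard deviations.
#' @param ar Lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @return A tibble of class `climate_series` with columns `century_bp`,
#'   `temperature`, `precipitation`.
#' @examples
#' cl <- gen_climate_series(1, 5000, 3500, events = data.frame(
#'   start_bp = 4200, end_bp = 4000, precip_multiplier = 0.8
#' ))
#' @export
gen_climate_series <- function(seed, start_bp, end_bp,
                               baseline_t = 13, baseline_p = 700,
                               trend_t = 0, trend_p = 0,
                               events = NULL,
                               noise_sd_t = 0, noise_sd_p = 0, ar = 0.5) {
  stopifnot(start_bp > end_bp)
  centuries <- seq(from = start_bp, to = end_bp, by = -100)
  n <- length(centuries)
  if (!is.null(events) && nrow(events)) {
    if (any(events$start_bp > start_bp | events$end_bp < end_bp - 99)) {
      abort_fmt("an event lies outside the series span %d-%d BP", start_bp, end_bp)
    }
  }
  ar1 <- function(sd) {
    if (sd == 0) return(rep(0, n))
    e <- numeric(n)
    innov <- stats::rnorm(n)
    e[1] <- sd * innov[1]
    for (i in seq_len(n)[-1]) e[i] <- ar * e[i - 1] + sd * sqrt(1 - ar^2) * innov[i]
    e
  }
  noise <- with_seed(seed, list(t = ar1(noise_sd_t), p = ar1(noise_sd_p)))
  elapsed <- (start_bp - centuries) / 1000
  temp <- baseline_t + trend_t * elapsed + noise$t
  prec <- baseline_p + trend_p * elapsed + noise$p
  if (!is.null(events) && nrow(events)) {
    for (i in seq_len(nrow(events))) {
      in_win <- centuries <= events$start_bp[i] & centuries >= events$end_bp[i]
      mult <- if ("precip_multiplier" %in% names(events))
        events$precip_multiplier[i] else 1
      shift <- if ("temp_shift" %in% names(events)) events$temp_shift[i] else 0
      if (is.na(mult)) mult <- 1
      if (is.na(shift)) shift <- 0
      prec[in_win] <- prec[in_win] * mult
      temp[in_win] <- temp[in_win] + shift
    }
  }
  if (any(prec < 0)) {
    warning("precipitation clipped to 0 for ", sum(prec < 0), " centuries")
    prec[prec < 0] <- 0
  }
  out <- tibble::tibble(century_bp = centuries, temperature = temp,
                        precipitation = prec)
  class(out) <- c("climate_series", class(out))
  attr(out, "events") <- events
  out
}
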