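# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Round half away from zero to the nearest integer
#'
#' Adjusted site counts use commercial ("half-up") rounding rather than
#' banker's rounding: 31.5 becomes 32 and 5897.5 becomes 5898. This is the
#' only rounding rule consistent with published adjusted-count tables.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @examples
#' round_half_up(c(31.5, 62.5, 49.125))
#' @export
round_half_up <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) + 0.5)
}

# Circular mean of angles in degrees; NA if no finite input.
circular_mean_deg <- function(deg) {
  deg <- deg[is.finite(deg)]
  if (length(deg) == 0L) return(NA_real_)
  rad <- deg * pi / 180
  ang <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  (ang + 360) %% 360
}

# Modal value with deterministic tie-break (lowest value wins).
modal_value <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  tab <- table(x)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  min(cand)
}

abort_fmt <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
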