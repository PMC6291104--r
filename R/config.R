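#' Study configuration
#'
#' Collects the tunable analysis parameters in one validated record:
#' catchment buffer radii in metres (200 m is the headline radius; 500 and
#' 1000 m are computed for sensitivity), the yield bin width for the
#' intensity regression (tFM/ha), the subsistence threshold below which
#' long-term mean yield is taken to be insufficient for subsistence
#' farming (tFM/ha), bootstrap and permutation replicate counts, and the
#' RNG seed recorded in every output.
#'
#' @param buffer_radii Numeric vector of catchment radii, metres.
#' @param bin_width Yield bin width, tFM/ha.
#' @param subsistence_threshold Yield threshold, tFM/ha.
#' @param bootstrap_reps,permutation_reps Positive replicate counts.
#' @param rng_seed Integer seed.
#' @return A list of class `study_config`.
#' @examples
#' study_config()
#' @export
study_config <- function(buffer_radii = c(200, 500, 1000),
                         bin_width = 0.1,
                         subsistence_threshold = 1.0,
                         bootstrap_reps = 1000,
                         permutation_reps = 1999,
                         rng_seed = 1L) {
  cfg <- list(buffer_radii = as.numeric(buffer_radii),
              bin_width = as.numeric(bin_width),
              subsistence_threshold = as.numeric(subsistence_threshold),
              bootstrap_reps = as.integer(bootstrap_reps),
              permutation_reps = as.integer(permutation_reps),
              rng_seed = as.integer(rng_seed))
  if (any(cfg$buffer_radii <= 0) || cfg$bin_width <= 0 ||
      cfg$subsistence_threshold <= 0 || cfg$bootstrap_reps <= 0 ||
      cfg$permutation_reps <= 0) {
    abort_fmt("all study_config parameters must be positive")
  }
  class(cfg) <- "study_config"
  cfg
}

#' Read or write a study configuration as YAML
#'
#' @param path File path.
#' @param config A `study_config` (for writing).
#' @return `load_study_config()` returns a validated `study_config`.
#' @export
load_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw[intersect(names(raw), names(formals(study_config)))])
}

#' @rdname load_study_config
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
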