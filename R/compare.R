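#' Median, midspread and bootstrap CI of a value set
#'
#' The distribution summary used on both sides of every landscape
#' comparison: median and quartiles by linear-interpolation quantiles
#' (R type 7), plus a percentile-bootstrap 95% confidence interval of the
#' median (fixed seed, `reps` resamples). A single value yields a
#' degenerate summary with all statistics equal. Identical inputs and
#' seed always give identical output.
#'
#' @param values Numeric vector, `n >= 1` after dropping NA.
#' @param seed Integer RNG seed for the bootstrap.
#' @param reps Bootstrap resamples.
#' @param source Label recorded in the `source` column.
#' @param conf Confidence level.
#' @return A one-row tibble: `source`, `n`, `median`, `q1`, `q3`,
#'   `ci_low`, `ci_high`.
#' @examples
#' summarize_distribution(1:9, seed = 1)
#' @export
summarize_distribution <- function(values, seed = 1L, reps = 1000,
                                   source = "values", conf = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) abort_fmt("cannot summarise an empty value set")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  if (length(values) == 1L) {
    ci <- c(values, values)
  } else {
    boots <- with_seed(seed, {
      idx <- matrix(sample.int(length(values), length(values) * reps,
                               replace = TRUE), ncol = reps)
      apply(idx, 2, function(i) stats::median(values[i]))
    })
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(a, 1 - a), type = 7))
  }
  tibble::tibble(source = source, n = length(values), median = q[2],
                 q1 = q[1], q3 = q[3], ci_low = ci[1], ci_high = ci[2])
}

#' Landscape versus exploited-fraction distribution comparison
#'
#' Contrasts the potential-yield distribution of the whole landscape with
#' that of the fraction exploited by the inhabitants of one period. The
#' landscape side summarises all non-nodata pixels of the period-mean
#' raster (optionally restricted by `mask`); the exploited side
#' summarises one value per occupying site — the catchment mean of the
#' same raster (see [catchment_yield_means()]). With zero sites only the
#' landscape row is returned and the median difference is `NA`.
#'
#' @param pm A `period_mean_raster`.
#' @param site_means Numeric vector of per-site catchment means, or a
#'   tibble with a `catchment_mean` column.
#' @param mask Optional `grid_raster`; cells with nodata or 0 are
#'   excluded from the landscape side.
#' @param seed,reps Bootstrap parameters (see [summarize_distribution()]).
#' @return A tibble of class `period_comparison` with up to two rows
#'   (`source` = `"landscape"`, `"exploited"`) and attribute
#'   `median_difference` (exploited minus landscape).
#' @export
exploited_vs_landscape <- function(pm, site_means, mask = NULL,
                                   seed = 1L, reps = 1000) {
  stopifnot(inherits(pm, "period_mean_raster"))
  vals <- pm$mean$values
  if (!is.null(mask)) {
    assert_aligned(pm$mean, mask)
    vals[is.na(mask$values) | mask$values == 0] <- NA
  }
  land <- summarize_distribution(vals[!is.na(vals)], seed = seed,
                                 reps = reps, source = "landscape")
  if (is.data.frame(site_means)) site_means <- site_means$catchment_mean
  site_means <- site_means[!is.na(site_means)]
  out <- if (length(site_means) == 0L) {
    land
  } else {
    expl <- summarize_distribution(site_means, seed = seed, reps = reps,
                                   source = "exploited")
    dplyr::bind_rows(land, expl)
  }
  out$period <- pm$period
  out$crop_label <- pm$crop_label
  attr(out, "median_difference") <- if (length(site_means)) {
    stats::median(site_means) - land$median
  } else {
    NA_real_
  }
  class(out) <- c("period_comparison", class(out))
  out
}

#' Centennial difference series between exploited fraction and landscape
#'
#' For every centennial step the cube covers: the landscape median of
#' that century's per-pixel mean yield, the exploited median over the
#' catchment means of the occupation/agricultural sites of the period
#' containing the century (a century on a period boundary belongs to the
#' older period), and their difference. The series is a step function at
#' period boundaries by construction — sites change only when the period
#' does. Centuries outside every period are reported with `NA` exploited
#' values.
#'
#' @param cube A `yield_cube` spanning the period table.
#' @param sites A `site_table`.
#' @param periods A `period_table`.
#' @param radius Catchment radius, metres.
#' @param step Step width in years (default 100).
#' @return A tibble: `century_bp`, `period`, `landscape_median`,
#'   `exploited_median`, `difference`, `n_sites`.
#' @export
difference_series <- function(cube, sites, periods, radius = 200,
                              step = 100) {
  stopifnot(inherits(cube, "yield_cube"), inherits(periods, "period_table"))
  centuries <- seq(max(cube$years), min(cube$years), by = -step)
  purrr::map_dfr(centuries, function(cb) {
    sel <- cube$years <= cb & cube$years > cb - step
    if (!any(sel)) sel <- which.min(abs(cube$years - cb))
    slab <- cube$data[, , sel, drop = FALSE]
    mu <- matrix(rowMeans(matrix(slab, prod(dim(slab)[1:2]), dim(slab)[3])),
                 dim(slab)[1], dim(slab)[2])
    # older period wins a boundary tie: first match in oldest-first order
    hit <- which(periods$start_bp >= cb & periods$end_bp <= cb)
    pname <- if (length(hit)) periods$name[hit[1]] else NA_character_
    land_med <- stats::median(mu[!is.na(mu)])
    if (is.na(pname)) {
      return(tibble::tibble(century_bp = cb, period = pname,
                            landscape_median = land_med,
                            exploited_median = NA_real_,
                            difference = NA_real_, n_sites = 0L))
    }
    pm <- structure(list(period = pname, crop_label = cube$crop_label,
                         mean = grid_raster(mu, cube$cell_size,
                                            cube$origin_x, cube$origin_y)),
                    class = "period_mean_raster")
    cm <- catchment_yield_means(sites, pm, radius)
    tibble::tibble(
      century_bp = cb, period = pname, landscape_median = land_med,
      exploited_median = if (nrow(cm)) stats::median(cm$catchment_mean) else NA_real_,
      difference = if (nrow(cm)) stats::median(cm$catchment_mean) - land_med else NA_real_,
      n_sites = nrow(cm)
    )
  })
}

#' Two-sided permutation test on a difference of means
#'
#' Distribution-free comparison of two value groups by their difference
#' of means. When the number of distinct group-A assignments
#' (`choose(nA + nB, nA)`) is at most 20,000 the permutation null is
#' enumerated exactly; otherwise `reps` Monte-Carlo permutations are
#' drawn under a fixed seed and the p-value includes the observed
#' statistic (add-one convention), which keeps the test valid.
#'
#' @param group_a,group_b Nonempty numeric vectors.
#' @param seed Integer RNG seed (Monte-Carlo path only).
#' @param reps Monte-Carlo permutations.
#' @return A one-row tibble: `observed_diff` (mean A minus mean B),
#'   `p_value`, `method` (`"exact"` or `"monte_carlo"`), `n_perm`.
#' @examples
#' permutation_compare(c(1, 2, 3), c(11, 12, 13))  # exact p = 0.1
#' @export
permutation_compare <- function(group_a, group_b, seed = 1L, reps = 1999) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na == 0L || nb == 0L) abort_fmt("both groups must be nonempty")
  pool <- c(group_a, group_b)
  obs <- mean(group_a) - mean(group_b)
  total <- sum(pool)
  n <- na + nb
  # diff of means is a monotone function of sum(group_a)
  diff_from_sum_a <- function(sa) sa / na - (total - sa) / nb
  n_comb <- choose(n, na)
  tol <- 1e-12 * max(1, abs(obs))
  if (n_comb <= 20000) {
    combs <- utils::combn(n, na)
    sums <- colSums(matrix(pool[combs], nrow = na))
    diffs <- diff_from_sum_a(sums)
    p <- mean(abs(diffs) >= abs(obs) - tol)
    tibble::tibble(observed_diff = obs, p_value = p, method = "exact",
                   n_perm = as.integer(n_comb))
  } else {
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(reps), function(r) {
        sa <- sum(pool[sample.int(n, na)])
        abs(diff_from_sum_a(sa)) >= abs(obs) - tol
      }, logical(1)))
    })
    tibble::tibble(observed_diff = obs,
                   p_value = (1 + exceed) / (reps + 1),
                   method = "monte_carlo", n_perm = as.integer(reps))
  }
}

#' Binned settlement-intensity regression on potential yield
#'
#' Bins the landscape by period-mean yield in increments of `bin_width`
#' (covering `[0, max]`), computes the landscape area of each bin
#' (cell count times cell area, km2), assigns each site to the bin of
#' its catchment-mean yield, and regresses settlement intensity
#' (sites/km2) on bin midpoints by least squares — by default weighted by
#' bin area so sparsely represented yield classes do not dominate the
#' fit; an unweighted switch is provided. Bins with zero landscape area
#' are dropped. With fewer than two nonempty bins the fit is marked
#' undefined rather than fabricated.
#'
#' @param pm A `period_mean_raster`.
#' @param site_means Per-site catchment mean yields (vector or tibble
#'   with `catchment_mean`).
#' @param bin_width Bin width, tFM/ha.
#' @param weighted Weight the fit by bin area (default TRUE).
#' @param mask Optional `grid_raster` restricting the landscape.
#' @return An object of class `intensity_regression`: a list with
#'   `bins` (tibble: `bin_low`, `bin_mid`, `bin_high`, `area_km2`,
#'   `site_count`, `intensity`), `slope`, `intercept`, `r_squared`,
#'   `weighted`, `defined`, `period`, `crop_label`.
#' @export
binned_intensity_regression <- function(pm, site_means, bin_width = 0.1,
                                        weighted = TRUE, mask = NULL) {
  stopifnot(inherits(pm, "period_mean_raster"), bin_width > 0)
  vals <- pm$mean$values
  if (!is.null(mask)) {
    assert_aligned(pm$mean, mask)
    vals[is.na(mask$values) | mask$values == 0] <- NA
  }
  vals <- vals[!is.na(vals)]
  if (is.data.frame(site_means)) site_means <- site_means$catchment_mean
  site_means <- site_means[!is.na(site_means)]
  edges <- seq(0, max(vals, site_means, 0) + bin_width, by = bin_width)
  cell_area_km2 <- (pm$mean$cell_size / 1000)^2
  land_bin <- findInterval(vals, edges, rightmost.closed = TRUE)
  site_bin <- findInterval(site_means, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  bins <- tibble::tibble(
    bin_low = edges[-length(edges)],
    bin_high = edges[-1],
    bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
    area_km2 = tabulate(land_bin, nb) * cell_area_km2,
    site_count = tabulate(site_bin, nb)
  )
  bins <- bins[bins$area_km2 > 0, ]
  bins$intensity <- bins$site_count / bins$area_km2
  defined <- nrow(bins) >= 2
  if (defined) {
    fit <- stats::lm(intensity ~ bin_mid, data = bins,
                     weights = if (weighted) bins$area_km2 else NULL)
    coefs <- stats::coef(fit)
    w <- if (weighted) bins$area_km2 else rep(1, nrow(bins))
    ss_tot <- sum(w * (bins$intensity - stats::weighted.mean(bins$intensity, w))^2)
    r2 <- if (ss_tot > 0) 1 - sum(w * stats::residuals(fit)^2) / ss_tot else 1
  } else {
    coefs <- c(NA_real_, NA_real_)
    r2 <- NA_real_
  }
  structure(
    list(bins = bins[c("bin_low", "bin_mid", "bin_high", "area_km2",
                       "site_count", "intensity")],
         slope = unname(coefs[2]), intercept = unname(coefs[1]),
         r_squared = r2, weighted = weighted, defined = defined,
         period = pm$period, crop_label = pm$crop_label,
         n_sites = length(site_means)),
    class = "intensity_regression"
  )
}

#' @export
print.intensity_regression <- function(x, ...) {
  cat(sprintf("<intensity_regression> %s / %s: %d bins, %d sites\n",
              x$period, x$crop_label, nrow(x$bins), x$n_sites))
  if (x$defined) {
    cat(sprintf("  intensity = %.4g + %.4g * PAgP  (R2 = %.3f, %s)\n",
                x$intercept, x$slope, x$r_squared,
                if (x$weighted) "area-weighted" else "unweighted"))
  } else {
    cat("  fit undefined (fewer than 2 nonempty bins)\n")
  }
  invisible(x)
}

#' Fraction of the landscape below a subsistence yield threshold
#'
#' Share of non-nodata cells whose period-mean yield falls strictly below
#' `threshold` — by default 1.0 tFM/ha, a rough ethnographically derived
#' bound on the long-term mean cereal yield able to sustain subsistence
#' farmers.
#'
#' @param pm A `period_mean_raster`.
#' @param threshold Yield threshold, tFM/ha (> 0).
#' @param mask Optional `grid_raster` restricting the landscape.
#' @return A single number in `[0, 1]`.
#' @export
subsistence_fraction <- function(pm, threshold = 1.0, mask = NULL) {
  stopifnot(inherits(pm, "period_mean_raster"), threshold > 0)
  vals <- pm$mean$values
  if (!is.null(mask)) {
    assert_aligned(pm$mean, mask)
    vals[is.na(mask$values) | mask$values == 0] <- NA
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  mean(vals < threshold)
}
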