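test_that("distribution summaries use interpolated quantiles and are seeded", {
  s <- summarize_distribution(1:9, seed = 4)
  expect_equal(s$median, 5)
  expect_equal(s$q1, 3)
  expect_equal(s$q3, 7)
  expect_true(s$ci_low <= s$median && s$median <= s$ci_high)

  const <- summarize_distribution(rep(2.5, 40), seed = 1)
  expect_equal(const$q1, 2.5)
  expect_equal(const$ci_low, 2.5)
  expect_equal(const$ci_high, 2.5)

  one <- summarize_distribution(3.3, seed = 1)
  expect_equal(one$ci_low, 3.3)
  expect_equal(one$n, 1)

  set.seed(99)
  v <- rnorm(200)
  expect_identical(summarize_distribution(v, seed = 7),
                   summarize_distribution(v, seed = 7))
  expect_error(summarize_distribution(numeric(0)), "empty")
})

test_that("exploited vs landscape comparisons behave at the extremes", {
  set.seed(12)
  vals <- matrix(runif(900, 0, 2), 30, 30)
  pm <- structure(list(period = "P1", crop_label = "W1",
                       mean = grid_raster(vals, 300)),
                  class = "period_mean_raster")

  # sites confined to the top decile: exploited median above landscape q3
  top <- quantile(vals, 0.9)
  cmp <- exploited_vs_landscape(pm, vals[vals >= top], seed = 2)
  land <- cmp[cmp$source == "landscape", ]
  expl <- cmp[cmp$source == "exploited", ]
  expect_gt(expl$median, land$q3)
  expect_gt(attr(cmp, "median_difference"), 0)

  # uniformly sampled cells: median difference inside the bootstrap CI width
  unif <- exploited_vs_landscape(pm, sample(vals, 150), seed = 3)
  eu <- unif[unif$source == "exploited", ]
  expect_lt(abs(attr(unif, "median_difference")), (eu$ci_high - eu$ci_low) * 2)

  # zero sites: landscape row only, difference absent
  none <- exploited_vs_landscape(pm, numeric(0), seed = 1)
  expect_equal(nrow(none), 1)
  expect_true(is.na(attr(none, "median_difference")))
})

test_that("sampling every cell as a site reproduces the landscape summary", {
  set.seed(13)
  vals <- matrix(runif(144, 0, 2), 12, 12)
  r <- grid_raster(vals, 300)
  pm <- structure(list(period = "P1", crop_label = "W1", mean = r),
                  class = "period_mean_raster")
  pt <- tiny_periods()
  cc <- cell_centers(r)
  all_sites <- site_table(tibble::tibble(
    id = sprintf("c%03d", 1:144),
    x = rep(cc$x, each = 12), y = rep(cc$y, times = 12),
    category = "occ_ag", occupied = purrr::map(1:144, ~"P1")
  ), pt)
  cm <- catchment_yield_means(all_sites, pm, radius = 100)  # < cell size
  expect_equal(sort(cm$catchment_mean), sort(as.vector(vals)))
  cmp <- exploited_vs_landscape(pm, cm, seed = 5)
  expect_equal(cmp$median[1], cmp$median[2])
  expect_equal(cmp$q1[1], cmp$q1[2])
})

test_that("permutation tests enumerate exactly when feasible", {
  r <- permutation_compare(c(1, 2, 3), c(11, 12, 13))
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 0.1)
  expect_equal(r$observed_diff, -10)

  same <- permutation_compare(c(4, 5, 6), c(6, 4, 5))
  expect_equal(same$observed_diff, 0)
  expect_equal(same$p_value, 1)

  set.seed(20)
  a <- rnorm(50); b <- rnorm(60)
  big <- permutation_compare(a, b, seed = 3, reps = 499)
  expect_equal(big$method, "monte_carlo")
  expect_identical(big, permutation_compare(a, b, seed = 3, reps = 499))
  expect_error(permutation_compare(numeric(0), 1:3), "nonempty")
})

test_that("binned intensity regression matches the closed form", {
  vals <- matrix(c(rep(0.05, 10), rep(0.15, 10), rep(0.25, 10)), 5, 6)
  pm <- structure(list(period = "P1", crop_label = "W1",
                       mean = grid_raster(vals, 1000)),
                  class = "period_mean_raster")
  site_means <- c(rep(0.15, 10), rep(0.25, 20))
  fit <- binned_intensity_regression(pm, site_means, bin_width = 0.1,
                                     weighted = FALSE)
  expect_equal(fit$bins$area_km2, c(10, 10, 10))
  expect_equal(fit$bins$site_count, c(0, 10, 20))
  expect_equal(fit$bins$intensity, c(0, 1, 2))
  expect_equal(fit$slope, 10)
  expect_equal(glance(fit)$r_squared, 1)
  expect_equal(nrow(tidy(fit)), 3)

  # equal areas: weighted and unweighted fits coincide
  fitw <- binned_intensity_regression(pm, site_means, bin_width = 0.1)
  expect_equal(fitw$slope, fit$slope)

  # a single occupied bin cannot support a fit
  uni <- structure(list(period = "P1", crop_label = "W1",
                        mean = grid_raster(matrix(0.55, 4, 4), 1000)),
                   class = "period_mean_raster")
  fit1 <- binned_intensity_regression(uni, rep(0.55, 5))
  expect_false(fit1$defined)
  expect_true(is.na(glance(fit1)$slope))
})

test_that("the subsistence fraction counts cells strictly below threshold", {
  mk <- function(v) structure(list(period = "P", crop_label = "W2",
                                   mean = grid_raster(v, 300)),
                              class = "period_mean_raster")
  expect_equal(subsistence_fraction(mk(matrix(2, 4, 4))), 0)
  half <- matrix(c(rep(0.5, 8), rep(1.5, 8)), 4, 4)
  expect_equal(subsistence_fraction(mk(half)), 0.5)
  expect_equal(subsistence_fraction(mk(matrix(1, 3, 3))), 0)  # strict
  set.seed(14)
  rv <- matrix(runif(100, 0, 2), 10, 10)
  expect_equal(subsistence_fraction(mk(rv), 0.8), mean(rv < 0.8))
})

test_that("difference series are step functions tied to the periodization", {
  pt <- tiny_periods()
  # constant cube: difference identically zero wherever sites exist
  arr <- array(1.3, c(8, 8, 21))
  cube <- yield_cube(arr, seq(5000, 3000, by = -100), 300, crop_label = "W1")
  sites <- site_table(tibble::tibble(
    id = c("a", "b"), x = c(450, 1350), y = c(450, 1350),
    category = "occ_ag", occupied = list(c("P1", "P2", "P3"), "P2")
  ), pt)
  ds <- difference_series(cube, sites, pt, radius = 100)
  expect_equal(nrow(ds), 21)
  expect_true(all(ds$difference == 0))
  expect_equal(unique(ds$n_sites[ds$period == "P2"]), 2)
  expect_equal(unique(ds$n_sites[ds$period == "P1"]), 1)
  # boundary century goes to the older period
  expect_equal(ds$period[ds$century_bp == 4300], "P1")
  expect_equal(ds$period[ds$century_bp == 3600], "P2")
})
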