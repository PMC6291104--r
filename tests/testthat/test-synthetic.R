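test_that("synthetic DEMs are reproducible, bounded and autocorrelated", {
  expect_equal(gen_dem(3, 16, 16, relief_amplitude = 0)$values,
               matrix(100, 16, 16))
  a <- gen_dem(11, 32, 32, relief_amplitude = 800)
  b <- gen_dem(11, 32, 32, relief_amplitude = 800)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, gen_dem(12, 32, 32, relief_amplitude = 800)$values))
  expect_equal(diff(range(a$values)), 800)
  expect_gte(min(a$values), 100)

  # empirical variogram increases with lag up to a range
  dem <- gen_dem(21, 64, 64, cell_size = 300, relief_amplitude = 800)
  set.seed(1)
  g <- oracle_variogram(dem$values, 300, lags = c(0, 600, 1500, 4000))
  expect_true(all(diff(g) > 0))
  expect_error(gen_dem(1, 0, 5), "positive")
})

test_that("D8 watercourses match geometry and a brute-force oracle", {
  # plane rising due east: each row drains straight west; accumulation
  # grows linearly toward the low edge, so only cells near it exceed a
  # high threshold
  plane <- grid_raster(outer(rep(0, 8), seq_len(10)) +
                         matrix(rep(seq_len(10), each = 8), 8, 10), 30)
  w <- gen_watercourses(plane, accumulation_threshold = 8)
  expect_equal(w$accumulation$values[3, ], 10:1)
  expect_true(all(which(w$mask$values == 1, arr.ind = TRUE)[, 2] <= 3))

  # V-shaped valley: a single trunk stream along the axis
  vv <- outer(rep(1, 9), abs(seq(-4, 4))) * 10 +
    matrix(rep(seq_len(9), each = 9), 9, 9) * 0.1
  valley <- grid_raster(vv, 30)
  wv <- gen_watercourses(valley, accumulation_threshold = 15)
  wet <- which(wv$mask$values == 1, arr.ind = TRUE)
  expect_true(all(wet[, 2] == 5))
  expect_gt(nrow(wet), 2)

  # threshold larger than the cell count -> no water anywhere
  none <- gen_watercourses(plane, accumulation_threshold = 81)
  expect_equal(sum(none$mask$values), 0)

  set.seed(31)
  z <- matrix(rnorm(100, 100, 15), 10, 10)
  z[, 1] <- z[, 1] - 50   # make the west edge the clear outlet
  w <- gen_watercourses(grid_raster(z, 30), accumulation_threshold = 5)
  expect_equal(w$accumulation$values, oracle_accumulation(z, "west"))
})

test_that("flat terrain drains in parallel lines to one edge", {
  flat <- gen_dem(1, 6, 6, relief_amplitude = 0)
  w <- gen_watercourses(flat, accumulation_threshold = 6)
  expect_equal(sum(w$mask$values), 6)          # the outlet edge column
  expect_true(all(w$accumulation$values[, 1] == 6))
})

test_that("climate series obey baselines, events and noise calibration", {
  quiet <- gen_climate_series(1, 5000, 4000, noise_sd_t = 0, noise_sd_p = 0)
  expect_equal(unique(quiet$temperature), 13)
  expect_equal(unique(quiet$precipitation), 700)

  ev <- data.frame(start_bp = 4200, end_bp = 4000, precip_multiplier = 0.8)
  with_ev <- gen_climate_series(1, 5000, 3500, events = ev,
                                noise_sd_t = 0, noise_sd_p = 0)
  in_win <- with_ev$century_bp <= 4200 & with_ev$century_bp >= 4000
  expect_equal(with_ev$precipitation[in_win], rep(700 * 0.8, 3))
  expect_equal(with_ev$precipitation[!in_win],
               rep(700, sum(!in_win)))

  # Monte-Carlo: per-century mean within 3 SE of the deterministic value
  reps <- 400
  sims <- sapply(seq_len(reps), function(r) {
    gen_climate_series(r, 5000, 4500, noise_sd_p = 40)$precipitation
  })
  se <- 40 / sqrt(reps)
  expect_true(all(abs(rowMeans(sims) - 700) < 3 * se))

  expect_error(
    gen_climate_series(1, 5000, 4500,
                       events = data.frame(start_bp = 9000, end_bp = 8000,
                                           precip_multiplier = 0.5)),
    "span"
  )
  expect_warning(
    gen_climate_series(1, 5000, 4500, baseline_p = 100,
                       events = data.frame(start_bp = 5000, end_bp = 4500,
                                           precip_multiplier = -2)),
    "clipped"
  )
})

test_that("the yield surrogate has the declared response structure", {
  expect_equal(surrogate_yield(13, 0), 0)                 # no water, no yield
  expect_equal(surrogate_yield(-5, 700), 0)               # below Tmin
  expect_equal(surrogate_yield(35, 700), 0)               # above Tmax
  expect_error(surrogate_yield(13, 700, crop_label = "maize"), "unknown crop")

  # monotone: nondecreasing in P, nonincreasing in slope beyond the knee
  p_grid <- seq(0, 1500, by = 50)
  y_p <- surrogate_yield(13, p_grid)
  expect_true(all(diff(y_p) >= 0))
  s_grid <- seq(5, 40, by = 1)
  y_s <- surrogate_yield(13, 700, slope = s_grid)
  expect_true(all(diff(y_s) <= 0))
  expect_equal(surrogate_yield(13, 700, slope = 3),
               surrogate_yield(13, 700, slope = 5))       # flat below knee

  # intensity registers differ only by Ymax: the ratio is algebraic
  pars <- crop_params()
  ratio <- pars$Ymax[pars$label == "W1"] / pars$Ymax[pars$label == "W2"]
  for (temp in c(5, 13, 20)) {
    for (p in c(150, 700)) {
      expect_equal(surrogate_yield(temp, p, 4, 0.8, "W1") /
                     surrogate_yield(temp, p, 4, 0.8, "W2"), ratio)
    }
  }
})

test_that("yield cubes respect climate, noise scale and determinism", {
  dem <- gen_dem(5, 12, 12, relief_amplitude = 300)
  soil <- gen_soil(6, dem, 2)
  slope <- slope_aspect(dem)$slope
  sf <- c("1" = 1, "2" = 0.8)

  flat_cl <- gen_climate_series(1, 5000, 4000)
  cube <- gen_yield_cube(7, dem, slope, soil, sf, flat_cl, "W1")
  expect_true(all(apply(cube$data, c(1, 2), function(v) length(unique(v))) == 1))

  ev <- data.frame(start_bp = 4500, end_bp = 4300, precip_multiplier = 0.8)
  cl <- gen_climate_series(1, 5000, 4000, events = ev)
  cube_ev <- gen_yield_cube(7, dem, slope, soil, sf, cl, "W1")
  med <- apply(cube_ev$data, 3, median)
  pre <- med[cube_ev$years > 4500]
  during <- med[cube_ev$years <= 4500 & cube_ev$years >= 4300]
  expect_true(all(during < min(pre)))

  # lognormal interannual noise: per-cell temporal CV ~ annual_noise_sd
  years <- seq(5000, 4901)   # 100 annual layers in one century
  noisy <- gen_yield_cube(8, dem, slope, soil, sf, flat_cl, "W1",
                          years = years, annual_noise_sd = 0.1)
  m <- matrix(noisy$data, 144, length(years))
  cv <- apply(m, 1, sd) / rowMeans(m)
  expect_lt(abs(median(cv) - 0.1) / 0.1, 0.1)

  expect_error(
    gen_yield_cube(7, dem, slope, soil, sf, flat_cl, years = seq(6000, 5500, -100)),
    "span"
  )
})

test_that("settlement histories recover the planted preference", {
  pt <- tiny_periods()
  dem <- gen_dem(9, 24, 24, cell_size = 300, relief_amplitude = 500)
  slope <- slope_aspect(dem)$slope
  soil <- gen_soil(10, dem, 2)
  cl <- gen_climate_series(11, 5000, 3000)
  cube <- gen_yield_cube(12, dem, slope, soil, c("1" = 1, "2" = 0.8), cl, "W1")
  pm <- period_mean_sigma(cube, pt[1, ])
  pms <- list(P1 = pm$mean)
  land_mean <- mean(pm$mean$values)
  land_med <- median(pm$mean$values)

  one_period <- function(beta, n, seed) {
    sc <- data.frame(period = "P1", n_sites = n, beta = beta,
                     p_persist = 1, frac_occ_ag = 1)
    gen_settlement_history(seed, sc, pms, pt)
  }

  # beta = 0 is uniform: chosen-cell mean within Monte-Carlo error
  draws <- sapply(1:30, function(s) {
    sites <- one_period(0, 80, s)
    mean(vapply(seq_len(nrow(sites)), function(i) {
      rc <- cell_at(pm$mean, sites$x[i], sites$y[i])
      pm$mean$values[rc[1], rc[2]]
    }, numeric(1)))
  })
  land_sd <- sd(pm$mean$values)
  se <- land_sd / sqrt(80) / sqrt(30)
  expect_lt(abs(mean(draws) - land_mean), 4 * se)

  # sign recovery at 200 sites: exploited median brackets the landscape median
  pos <- one_period(2, 200, 77)
  neg <- one_period(-2, 200, 77)
  med_of <- function(sites) {
    median(catchment_yield_means(sites, pm, 200)$catchment_mean)
  }
  expect_gt(med_of(pos), land_med)
  expect_lt(med_of(neg), land_med)

  # full persistence with constant n: no churn in the second period
  sc <- data.frame(period = c("P1", "P2"), n_sites = 50, beta = 0,
                   p_persist = 1, frac_occ_ag = 1)
  hist2 <- gen_settlement_history(13, sc, list(P1 = pm$mean, P2 = pm$mean), pt)
  tr <- classify_transitions(hist2, pt)
  expect_equal(tr$new[2], 0)
  expect_equal(tr$abandoned[2], 0)

  expect_error(one_period(0, 10000, 1), "free land cells")
})
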