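test_that("period mean/sigma rasters reduce cubes correctly", {
  pt <- tiny_periods()
  layer <- matrix(runif(36, 0, 2), 6, 6)
  arr <- array(rep(layer, 4), c(6, 6, 4))
  cube <- yield_cube(arr, c(5000, 4800, 4600, 4400), 300)
  pm <- period_mean_sigma(cube, pt[1, ])    # P1: 5000-4300 BP
  expect_equal(pm$mean$values, layer)
  expect_equal(pm$sigma$values, matrix(0, 6, 6))
  expect_equal(pm$n_years, 4)

  two <- array(c(matrix(2, 2, 2), matrix(4, 2, 2)), c(2, 2, 2))
  cube2 <- yield_cube(two, c(5000, 4900), 300)
  pm2 <- period_mean_sigma(cube2, pt[1, ])
  expect_equal(pm2$mean$values, matrix(3, 2, 2))
  expect_equal(pm2$sigma$values, matrix(1, 2, 2))   # population SD

  # 50 random layers against a simple two-pass oracle
  set.seed(5)
  arr <- array(runif(4 * 4 * 50, 0, 3), c(4, 4, 50))
  cube50 <- yield_cube(arr, seq(5000, by = -10, length.out = 50), 300)
  pm50 <- period_mean_sigma(cube50, pt[1, ])
  for (r in 1:4) for (c in 1:4) {
    v <- arr[r, c, ]
    expect_equal(pm50$mean$values[r, c], mean(v), tolerance = 1e-9)
    expect_equal(pm50$sigma$values[r, c], sqrt(mean((v - mean(v))^2)),
                 tolerance = 1e-9)
  }

  expect_error(period_mean_sigma(cube, pt[3, ]), "P3")

  # nodata propagates through the temporal reduction
  holey <- arr
  holey[2, 2, 7] <- NA
  pmh <- period_mean_sigma(yield_cube(holey, cube50$years, 300), pt[1, ])
  expect_true(is.na(pmh$mean$values[2, 2]))
  expect_false(anyNA(pmh$mean$values[-2, ]))
})

test_that("buffer pixel sets follow the centre-in-circle rule", {
  r30 <- grid_raster(matrix(0, 40, 40), 30)
  cc <- cell_centers(r30)

  # radius below half a cell at a cell centre: exactly that cell
  expect_identical(pixels_in_buffer(r30, cc$x[20], cc$y[20], 10),
                   (20L - 1L) * 40L + 20L)

  # 200 m buffer on the 30 m grid matches the brute-force oracle
  for (pt in list(c(20, 20), c(8, 33), c(33, 8))) {
    x <- cc$x[pt[2]]; y <- cc$y[pt[1]]
    got <- pixels_in_buffer(r30, x, y, 200)
    expect_identical(got, oracle_buffer(r30, x, y, 200))
    expect_equal(length(got), 140, tolerance = 0.05)  # ~ pi 200^2 / 900
  }

  # off-centre points too
  got <- pixels_in_buffer(r30, 431.7, 512.9, 200)
  expect_identical(got, oracle_buffer(r30, 431.7, 512.9, 200))

  # fallback: a 200 m catchment on a 300 m grid still has >= 1 cell
  r300 <- grid_raster(matrix(0, 6, 6), 300)
  corner <- pixels_in_buffer(r300, 40, 40, 100)
  expect_length(corner, 1)

  # radius monotonicity
  s1 <- pixels_in_buffer(r30, 600, 600, 100)
  s2 <- pixels_in_buffer(r30, 600, 600, 250)
  expect_true(all(s1 %in% s2))
  expect_error(pixels_in_buffer(r30, -50, 600, 100), "outside")
})

test_that("catchment summaries match a masked-average oracle", {
  set.seed(6)
  elev <- grid_raster(matrix(rnorm(400, 300, 40), 20, 20), 30)
  yield <- grid_raster(matrix(runif(400, 0, 2), 20, 20), 30)
  yield$values[sample(400, 25)] <- NA
  pt <- tiny_periods()
  sites <- site_table(tibble::tibble(
    id = sprintf("s%d", 1:6),
    x = runif(6, 60, 540), y = runif(6, 60, 540),
    category = "occ_ag", occupied = list("P1")
  ), pt)

  out <- summarize_catchments(sites, list(elevation = elev, yield = yield),
                              radius = 100, period = "P1")
  for (i in 1:6) {
    cells <- oracle_buffer(elev, sites$x[i], sites$y[i], 100)
    for (v in c("elevation", "yield")) {
      vals <- (if (v == "elevation") elev else yield)$values[cells]
      vals <- vals[!is.na(vals)]
      got <- out[out$site_id == sites$id[i] & out$variable == v, ]
      expect_equal(got$value[got$stat == "mean"], mean(vals), tolerance = 1e-9)
      expect_equal(got$value[got$stat == "median"], median(vals), tolerance = 1e-9)
      expect_equal(got$value[got$stat == "n"], length(vals))
    }
  }
})

test_that("constant and mixed rasters give closed-form summaries", {
  pt <- tiny_periods()
  const <- grid_raster(matrix(5, 10, 10), 30)
  sites <- site_table(tibble::tibble(
    id = "s1", x = 150, y = 150, category = "occ_ag", occupied = list("P1")
  ), pt)
  out <- summarize_catchments(sites, list(v = const), radius = 100)
  expect_equal(out$value[out$stat == "mean"], 5)
  expect_equal(out$value[out$stat == "median"], 5)
  expect_equal(out$value[out$stat == "sd"], 0)

  # half the buffer at 1, half at 3 -> mean 2
  half <- matrix(1, 4, 4); half[, 3:4] <- 3
  hr <- grid_raster(half, 100)
  out <- summarize_catchments(
    tibble::tibble(id = "s", x = 200, y = 200),
    list(v = hr), radius = 250
  )
  expect_equal(out$value[out$stat == "mean"], 2)
})

test_that("aspect uses circular means and soil the lowest-code mode", {
  asp <- grid_raster(matrix(c(350, 10, 350, 10), 2, 2), 100)
  soil <- grid_raster(matrix(c(2, 1, 1, 2), 2, 2), 100)
  out <- summarize_catchments(
    tibble::tibble(id = "s", x = 100, y = 100),
    list(aspect = asp, soil_class = soil), radius = 300
  )
  expect_equal(out$value[out$variable == "aspect" & out$stat == "mean"], 0)
  expect_equal(out$value[out$variable == "soil_class" & out$stat == "mode"], 1)

  # a variable that is all nodata in the buffer is flagged absent, not zero
  hole <- grid_raster(matrix(NA_real_, 2, 2), 100)
  out <- summarize_catchments(
    tibble::tibble(id = "s", x = 100, y = 100),
    list(v = hole), radius = 300
  )
  expect_equal(out$value[out$stat == "n"], 0)
  expect_false("mean" %in% out$stat)
})
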