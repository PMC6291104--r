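#' Generate a spatially autocorrelated synthetic elevation model
#'
#' Builds a fractal terrain surface by spectral synthesis: white Gaussian
#' noise is filtered in the frequency domain with a power-law
#' (`1/f^roughness`) amplitude envelope and inverse-transformed, producing
#' the long-range spatial autocorrelation characteristic of real
#' topography. The surface is then rescaled so that its total relief
#' equals `relief_amplitude` above `base_elevation`. With
#' `relief_amplitude = 0` the result is a flat raster at `base_elevation`.
#' Output is fully deterministic for a fixed seed.
#'
#' @param seed Integer RNG seed.
#' @param nrows,ncols Grid dimensions (positive).
#' @param cell_size Cell edge, metres.
#' @param relief_amplitude Total relief (max - min), metres.
#' @param base_elevation Elevation of the lowest cell, metres.
#' @param roughness Spectral exponent; larger values give smoother terrain.
#' @param origin_x,origin_y Lower-left corner coordinates, metres.
#' @return A `grid_raster` labelled `"elevation"`.
#' @examples
#' dem <- gen_dem(1, 32, 32, cell_size = 300, relief_amplitude = 600)
#' @export
gen_dem <- function(seed, nrows, ncols, cell_size = 300,
                    relief_amplitude = 800, base_elevation = 100,
                    roughness = 1.6, origin_x = 0, origin_y = 0) {
  if (nrows <= 0 || ncols <= 0) abort_fmt("grid dimensions must be positive")
  if (relief_amplitude < 0) abort_fmt("relief_amplitude must be >= 0")
  field <- with_seed(seed, {
    noise <- matrix(stats::rnorm(nrows * ncols), nrows, ncols)
    if (relief_amplitude == 0 || nrows * ncols == 1L) {
      matrix(0, nrows, ncols)
    } else {
      fr <- ifelse(seq_len(nrows) - 1 <= nrows / 2,
                   seq_len(nrows) - 1, seq_len(nrows) - 1 - nrows) / nrows
      fc <- ifelse(seq_len(ncols) - 1 <= ncols / 2,
                   seq_len(ncols) - 1, seq_len(ncols) - 1 - ncols) / ncols
      f <- sqrt(outer(fr^2, fc^2, `+`))
      filt <- ifelse(f > 0, f^(-roughness), 0)
      Re(stats::fft(stats::fft(noise) * filt, inverse = TRUE)) / (nrows * ncols)
    }
  })
  rng <- range(field)
  if (diff(rng) > 0) {
    field <- (field - rng[1]) / diff(rng) * relief_amplitude
  }
  grid_raster(field + base_elevation, cell_size = cell_size,
              origin_x = origin_x, origin_y = origin_y, label = "elevation")
}

#' Generate a categorical soil-class raster
#'
#' A smooth random field (spectral synthesis with a steep exponent) is cut
#' at quantiles into `n_classes` contiguous soil classes coded `1:n`.
#' Classes are carriers for a user-supplied class-to-factor map consumed
#' by the yield surrogate; no pedogenesis is modelled.
#'
#' @param seed Integer RNG seed.
#' @param dem A `grid_raster` supplying the target geometry.
#' @param n_classes Number of soil classes.
#' @return A `grid_raster` labelled `"soil_class"` with values in
#'   `1:n_classes`.
#' @export
gen_soil <- function(seed, dem, n_classes = 3) {
  stopifnot(inherits(dem, "grid_raster"), n_classes >= 1)
  base <- gen_dem(seed, nrow(dem$values), ncol(dem$values),
                  cell_size = dem$cell_size, relief_amplitude = 1,
                  base_elevation = 0, roughness = 2.5,
                  origin_x = dem$origin_x, origin_y = dem$origin_y)
  v <- base$values
  if (n_classes == 1L || diff(range(v)) == 0) {
    cls <- matrix(1, nrow(v), ncol(v))
  } else {
    qs <- stats::quantile(v, probs = seq(0, 1, length.out = n_classes + 1))
    cls <- matrix(as.numeric(cut(v, breaks = unique(qs), include.lowest = TRUE)),
                  nrow(v), ncol(v))
  }
  grid_raster(cls, cell_size = dem$cell_size, origin_x = dem$origin_x,
              origin_y = dem$origin_y, label = "soil_class")
}

#' Extract synthetic watercourses by D8 flow routing
#'
#' Routes flow by steepest descent to one of the 8 neighbours (D8) and
#' accumulates contributing-cell counts (each cell contributes itself plus
#' everything upstream). Cells whose count reaches
#' `accumulation_threshold` are flagged as water. Flats are resolved by an
#' infinitesimal epsilon tilt toward the lowest frame edge (ties broken
#' west, east, south, north), so a perfectly flat surface drains in
#' parallel straight lines to that edge — the documented degenerate case.
#'
#' @param dem A `grid_raster` with no nodata cells.
#' @param accumulation_threshold Minimum contributing-cell count for a
#'   cell to be classed as water.
#' @return A list with `mask` (0/1 `grid_raster`), `accumulation`
#'   (`grid_raster` of contributing-cell counts) and `streams` (a tibble
#'   of flow segments `x, y, xend, yend, accumulation` for water cells,
#'   usable directly as a line vector set).
#' @export
gen_watercourses <- function(dem, accumulation_threshold) {
  stopifnot(inherits(dem, "grid_raster"))
  z <- dem$values
  if (anyNA(z)) abort_fmt("DEM must have no nodata cells inside the frame")
  nr <- nrow(z); nc <- ncol(z)
  # epsilon tilt toward the lowest frame edge resolves flats deterministically
  edge_means <- c(west = mean(z[, 1]), east = mean(z[, nc]),
                  south = mean(z[nr, ]), north = mean(z[1, ]))
  target <- names(edge_means)[which.min(edge_means)]
  dist_to_edge <- switch(target,
    west  = matrix(rep(seq_len(nc) - 1, each = nr), nr, nc),
    east  = matrix(rep(nc - seq_len(nc), each = nr), nr, nc),
    south = matrix(rep(nr - seq_len(nr), times = nc), nr, nc),
    north = matrix(rep(seq_len(nr) - 1, times = nc), nr, nc))
  eps <- max(diff(range(z)), 1) * 1e-9
  zt <- z + eps * dist_to_edge

  # D8 receivers: neighbour with the greatest positive drop / distance
  dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  dd <- sqrt(dr^2 + dc^2)
  receiver <- integer(nr * nc)  # linear index of downstream cell, 0 = outlet
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      best <- 0; best_k <- 0L
      for (k in 1:8) {
        rr <- r + dr[k]; cc <- c + dc[k]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        drop <- (zt[r, c] - zt[rr, cc]) / dd[k]
        if (drop > best) { best <- drop; best_k <- k }
      }
      receiver[(c - 1) * nr + r] <- if (best_k == 0L) 0L else
        (c + dc[best_k] - 1L) * nr + (r + dr[best_k])
    }
  }

  acc <- rep(1, nr * nc)
  for (i in order(zt, decreasing = TRUE)) {
    if (receiver[i] > 0L) acc[receiver[i]] <- acc[receiver[i]] + acc[i]
  }
  acc_m <- matrix(acc, nr, nc)
  mask <- (acc_m >= accumulation_threshold) * 1

  cc <- cell_centers(dem)
  wet <- which(mask == 1)
  streams <- tibble::tibble(
    x = cc$x[(wet - 1) %/% nr + 1],
    y = cc$y[(wet - 1) %% nr + 1],
    xend = NA_real_, yend = NA_real_,
    accumulation = acc[wet]
  )
  has_rec <- receiver[wet] > 0L
  rec <- receiver[wet[has_rec]]
  streams$xend[has_rec] <- cc$x[(rec - 1) %/% nr + 1]
  streams$yend[has_rec] <- cc$y[(rec - 1) %% nr + 1]

  list(
    mask = grid_raster(mask, dem$cell_size, dem$origin_x, dem$origin_y,
                       label = "water_mask"),
    accumulation = grid_raster(acc_m, dem$cell_size, dem$origin_x,
                               dem$origin_y, label = "flow_accumulation"),
    streams = streams
  )
}
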