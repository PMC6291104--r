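#' Crop parameter registry for the yield surrogate
#'
#' Registered response parameters for the built-in crop/intensity labels:
#' W1/W2 (wheat under maximally versus minimally intensive preindustrial
#' management) and P1/P2 (the analogous pulse labels). Within a crop the
#' two intensity registers share every response parameter and differ only
#' in the yield ceiling `Ymax`, so their yield ratio is exactly the
#' configured `Ymax` ratio everywhere — the intensification gap is a pure
#' scaling that dwarfs climate-driven swings. The surrogate is an explicit
#' stand-in for a process-based agro-ecosystem model, reproducing only the
#' qualitative structure the downstream analysis needs (two intensity
#' registers, climate sensitivity, spatial heterogeneity), not crop
#' physiology.
#'
#' @param extra Optional data frame of additional rows with the same
#'   columns, appended to the registry.
#' @return A tibble with columns `label`, `Ymax` (tFM/ha), `Tmin`, `Topt`,
#'   `Tmax` (degrees C), `P_half` (mm/yr), `slope_knee` (degrees),
#'   `slope_rate` (per degree).
#' @export
crop_params <- function(extra = NULL) {
  base <- tibble::tibble(
    label = c("W1", "W2", "P1", "P2"),
    Ymax = c(2.5, 0.9, 2.0, 0.7),
    Tmin = c(0, 0, 2, 2),
    Topt = c(14, 14, 16, 16),
    Tmax = c(30, 30, 32, 32),
    P_half = c(250, 250, 300, 300),
    slope_knee = c(5, 5, 5, 5),
    slope_rate = c(0.05, 0.05, 0.05, 0.05)
  )
  if (!is.null(extra)) base <- dplyr::bind_rows(base, tibble::as_tibble(extra))
  base
}

# triangular temperature response on [Tmin, Topt, Tmax], 0 outside
temp_response <- function(temp, tmin, topt, tmax) {
  up <- (temp - tmin) / (topt - tmin)
  down <- (tmax - temp) / (tmax - topt)
  pmax(0, pmin(up, down, 1))
}

#' Climate- and terrain-driven potential-yield surrogate
#'
#' Computes potential agricultural yield (tFM/ha) as a separable response
#' surface: a yield ceiling scaled by a triangular temperature response, a
#' saturating (Michaelis-type) water response, a linear slope penalty
#' beyond a knee, and a soil factor:
#' \deqn{Y = Y_{max} \cdot tri(T) \cdot \frac{P}{P + P_{1/2}} \cdot
#'   \max(0, 1 - \max(0, s - s_{knee}) \cdot r) \cdot soil}
#' The saturating water response avoids yield cliffs at climate-event
#' boundaries. All arguments are vectorised and recycled.
#'
#' @param temperature Annual-mean temperature, degrees C.
#' @param precipitation Annual precipitation, mm/yr (>= 0).
#' @param slope Terrain slope, degrees.
#' @param soil_factor Multiplier in `[0, 1]`.
#' @param crop_label A registered label (see [crop_params()]).
#' @param params Parameter registry (defaults to [crop_params()]).
#' @return Numeric yields, tFM/ha, always >= 0.
#' @examples
#' surrogate_yield(13, 700, slope = 2, crop_label = "W1")
#' @export
surrogate_yield <- function(temperature, precipitation, slope = 0,
                            soil_factor = 1, crop_label = "W1",
                            params = crop_params()) {
  p <- params[params$label == crop_label, ]
  if (nrow(p) != 1L) {
    abort_fmt("unknown crop label '%s'; registered: %s", crop_label,
              paste(params$label, collapse = ", "))
  }
  if (any(!is.finite(temperature)) || any(!is.finite(precipitation))) {
    abort_fmt("temperature and precipitation must be finite")
  }
  water <- precipitation / (precipitation + p$P_half)
  terr <- pmax(0, 1 - pmax(0, slope - p$slope_knee) * p$slope_rate)
  y <- p$Ymax * temp_response(temperature, p$Tmin, p$Topt, p$Tmax) *
    water * terr * soil_factor
  pmax(0, y)
}

#' Time-indexed stack of yield rasters for one crop label
#'
#' A `yield_cube` holds one aligned yield layer per year for a single
#' crop/intensity label, years strictly decreasing in BP (time moving
#' forward), values in tFM/ha and nonnegative.
#'
#' @param data Numeric array `nrows x ncols x n_years` (NA = nodata).
#' @param years Integer years BP, strictly decreasing.
#' @param cell_size,origin_x,origin_y Grid geometry (see [grid_raster()]).
#' @param crop_label Crop/intensity label.
#' @return An object of class `yield_cube`.
#' @export
yield_cube <- function(data, years, cell_size, origin_x = 0, origin_y = 0,
                       crop_label = "W1") {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  years <- as.integer(years)
  if (dim(data)[3] != length(years)) {
    abort_fmt("cube has %d layers but %d years", dim(data)[3], length(years))
  }
  if (length(years) > 1 && any(diff(years) >= 0)) {
    abort_fmt("years must be strictly decreasing in BP")
  }
  if (any(data[!is.na(data)] < 0)) abort_fmt("yield values must be >= 0")
  structure(
    list(data = data, years = years, cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         crop_label = crop_label, units = "tFM/ha"),
    class = "yield_cube"
  )
}

#' @export
print.yield_cube <- function(x, ...) {
  cat(sprintf("<yield_cube> %s: %d x %d cells, %d years (%d-%d BP), %s\n",
              x$crop_label, dim(x$data)[1], dim(x$data)[2], length(x$years),
              max(x$years), min(x$years), x$units))
  invisible(x)
}

#' Extract one year of a yield cube as a raster
#'
#' @param cube A `yield_cube`.
#' @param year A year present in `cube$years`.
#' @return A `grid_raster`.
#' @export
cube_layer <- function(cube, year) {
  i <- match(year, cube$years)
  if (is.na(i)) abort_fmt("year %d BP not present in cube", year)
  grid_raster(cube$data[, , i], cube$cell_size, cube$origin_x, cube$origin_y,
              label = sprintf("%s %d BP", cube$crop_label, year))
}

#' Generate a synthetic yield cube from terrain and climate
#'
#' For each requested year the cell yield is the deterministic surrogate
#' response to that year's century climate (temperature lapsed with
#' elevation at `lapse_rate`) and the cell's slope and soil factor,
#' multiplied by a mean-1 lognormal interannual factor whose coefficient
#' of variation is `annual_noise_sd`. With the same seed, cubes for
#' different crop labels receive identical noise realisations, so
#' intensity-register ratios are noise-free. Fully reproducible per seed.
#'
#' @param seed Integer RNG seed.
#' @param dem Elevation `grid_raster`.
#' @param slope Slope `grid_raster` (degrees), aligned with `dem`.
#' @param soil Soil-class `grid_raster`, aligned with `dem`.
#' @param soil_factors Named numeric map from soil class to factor in
#'   `[0, 1]`.
#' @param climate A `climate_series` covering all requested years.
#' @param crop_label Registered crop label.
#' @param years Integer years BP (strictly decreasing); default the
#'   climate series' centuries.
#' @param annual_noise_sd Interannual coefficient of variation (>= 0).
#' @param lapse_rate Temperature lapse with elevation, degrees C per metre.
#' @param params Crop registry.
#' @return A `yield_cube`.
#' @export
gen_yield_cube <- function(seed, dem, slope, soil, soil_factors, climate,
                           crop_label = "W1", years = NULL,
                           annual_noise_sd = 0, lapse_rate = 0.0065,
                           params = crop_params()) {
  assert_aligned(dem, slope, soil)
  if (is.null(years)) years <- climate$century_bp
  years <- as.integer(years)
  cent <- 100L * as.integer(round(years / 100))
  if (any(!cent %in% climate$century_bp)) {
    abort_fmt("climate series does not span requested years (%d-%d BP)",
              max(years), min(years))
  }
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  elev <- dem$values
  t_offset <- -lapse_rate * (elev - min(elev, na.rm = TRUE))
  sf <- matrix(unname(soil_factors[as.character(soil$values)]), nr, nc)
  if (anyNA(sf[!is.na(soil$values)])) {
    abort_fmt("soil_factors is missing a class present in the soil raster")
  }
  data <- with_seed(seed, {
    arr <- array(NA_real_, c(nr, nc, length(years)))
    sdlog <- sqrt(log(1 + annual_noise_sd^2))
    for (i in seq_along(years)) {
      row <- climate[climate$century_bp == cent[i], ]
      base <- surrogate_yield(row$temperature + t_offset, row$precipitation,
                              slope$values, sf, crop_label, params)
      noise <- if (annual_noise_sd > 0) {
        exp(matrix(stats::rnorm(nr * nc, -sdlog^2 / 2, sdlog), nr, nc))
      } else 1
      arr[, , i] <- base * noise
    }
    arr
  })
  yield_cube(data, years, dem$cell_size, dem$origin_x, dem$origin_y,
             crop_label)
}
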