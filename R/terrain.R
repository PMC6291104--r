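# 3x3 neighbourhood views with nearest-neighbour edge padding.
# Returns the 8 shifted matrices named by compass position plus centre.
neighborhood_views <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) abort_fmt("raster must be at least 3 x 3")
  zp <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  rows <- list(top = seq_len(nr), mid = seq_len(nr) + 1, bot = seq_len(nr) + 2)
  cols <- list(lft = seq_len(nc), ctr = seq_len(nc) + 1, rgt = seq_len(nc) + 2)
  list(
    nw = zp[rows$top, cols$lft], n = zp[rows$top, cols$ctr], ne = zp[rows$top, cols$rgt],
    w  = zp[rows$mid, cols$lft], e = zp[rows$mid, cols$rgt],
    sw = zp[rows$bot, cols$lft], s = zp[rows$bot, cols$ctr], se = zp[rows$bot, cols$rgt],
    c  = z
  )
}

#' Slope and aspect from an elevation raster
#'
#' Computes slope and aspect by Horn's 8-neighbour weighted finite
#' differences, the de facto standard for gridded elevation models. Slope
#' is the arctangent of the gradient magnitude, in degrees; aspect is the
#' compass azimuth of the downslope direction, degrees clockwise from
#' north in `[0, 360)`, and nodata wherever the cell is locally flat
#' (slope exactly 0). Edge cells are handled by nearest-neighbour padding.
#'
#' @param dem A `grid_raster` with at least a 3 x 3 extent.
#' @return A list of two aligned `grid_raster`s, `slope` (degrees) and
#'   `aspect` (degrees).
#' @examples
#' plane <- grid_raster(outer(rep(1, 5), 1:5) * 30, cell_size = 30)
#' slope_aspect(plane)$slope$values[3, 3]  # 45 degrees
#' @export
slope_aspect <- function(dem) {
  stopifnot(inherits(dem, "grid_raster"))
  v <- neighborhood_views(dem$values)
  cs <- dem$cell_size
  dzdx <- ((v$ne + 2 * v$e + v$se) - (v$nw + 2 * v$w + v$sw)) / (8 * cs)
  dzdy <- ((v$nw + 2 * v$n + v$ne) - (v$sw + 2 * v$s + v$se)) / (8 * cs)
  grad <- sqrt(dzdx^2 + dzdy^2)
  slope <- atan(grad) * 180 / pi
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  aspect[!is.na(grad) & grad == 0] <- NA_real_
  list(
    slope = grid_raster(slope, cs, dem$origin_x, dem$origin_y, label = "slope"),
    aspect = grid_raster(aspect, cs, dem$origin_x, dem$origin_y, label = "aspect")
  )
}

#' Terrain ruggedness index
#'
#' Per cell, the square root of the summed squared elevation differences
#' between the cell and its 8 neighbours (the Riley formulation). Zero on
#' locally constant terrain; a 1 m spike on a plain scores `sqrt(8)`.
#' Edge cells use nearest-neighbour padding.
#'
#' @param dem A `grid_raster` with at least a 3 x 3 extent.
#' @return A `grid_raster` labelled `"tri"` (metres).
#' @export
tri <- function(dem) {
  stopifnot(inherits(dem, "grid_raster"))
  v <- neighborhood_views(dem$values)
  ss <- (v$c - v$nw)^2 + (v$c - v$n)^2 + (v$c - v$ne)^2 +
    (v$c - v$w)^2 + (v$c - v$e)^2 +
    (v$c - v$sw)^2 + (v$c - v$s)^2 + (v$c - v$se)^2
  grid_raster(sqrt(ss), dem$cell_size, dem$origin_x, dem$origin_y,
              label = "tri")
}

#' Euclidean distance to the nearest water cell
#'
#' Exact straight-line distance (metres) from every cell centre to the
#' nearest water-cell centre. Water cells themselves score 0. Straight-line
#' rather than cost or flow distance: no transport model is assumed.
#'
#' @param water_mask A `grid_raster` with 1 on water cells, 0 (or NA)
#'   elsewhere; at least one water cell required.
#' @return A `grid_raster` labelled `"distance_to_water"`.
#' @export
distance_to_water <- function(water_mask) {
  stopifnot(inherits(water_mask, "grid_raster"))
  m <- water_mask$values
  wet <- which(!is.na(m) & m == 1)
  if (length(wet) == 0L) abort_fmt("water mask contains no water cells")
  nr <- nrow(m)
  cc <- cell_centers(water_mask)
  cx <- cc$x[(seq_along(m) - 1L) %/% nr + 1L]
  cy <- cc$y[(seq_along(m) - 1L) %% nr + 1L]
  wx <- cx[wet]; wy <- cy[wet]
  d2 <- rep(Inf, length(m))
  for (k in seq_along(wet)) {
    d2 <- pmin(d2, (cx - wx[k])^2 + (cy - wy[k])^2)
  }
  grid_raster(matrix(sqrt(d2), nr, ncol(m)), water_mask$cell_size,
              water_mask$origin_x, water_mask$origin_y,
              label = "distance_to_water")
}

#' Assemble the static terrain covariate stack
#'
#' Derives every static per-cell covariate used in catchment summaries
#' from an elevation model, a water mask and a soil-class raster:
#' elevation, slope, aspect, terrain ruggedness, distance to fresh water,
#' and soil class, all mutually aligned.
#'
#' @param dem Elevation `grid_raster`.
#' @param water_mask Water mask `grid_raster`, aligned with `dem`.
#' @param soil Soil-class `grid_raster`, aligned with `dem`.
#' @return A named list of aligned `grid_raster`s of class
#'   `terrain_stack`: `elevation`, `slope`, `aspect`, `tri`,
#'   `dist_water`, `soil_class`.
#' @export
terrain_stack <- function(dem, water_mask, soil) {
  assert_aligned(dem, water_mask, soil)
  sa <- slope_aspect(dem)
  out <- list(
    elevation = dem,
    slope = sa$slope,
    aspect = sa$aspect,
    tri = tri(dem),
    dist_water = distance_to_water(water_mask),
    soil_class = soil
  )
  class(out) <- "terrain_stack"
  out
}
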