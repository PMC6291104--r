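#' Per-pixel temporal mean and standard deviation over a period
#'
#' Reduces a yield cube to the two rasters used throughout the
#' comparisons: the per-pixel arithmetic mean and the per-pixel
#' *population* standard deviation of annual yield over the years a
#' period spans. A year `y` belongs to a period when
#' `start_bp >= y > end_bp`. Nodata propagates: a pixel that is nodata in
#' any selected year is nodata in both outputs. Population (divide by n)
#' rather than sample SD is used so closed-form checks are exact.
#'
#' @param cube A `yield_cube`.
#' @param period A one-row slice of a `period_table` (or any list with
#'   `name`, `start_bp`, `end_bp`).
#' @return A list of class `period_mean_raster` with elements `period`,
#'   `crop_label`, `mean` and `sigma` (aligned `grid_raster`s), and
#'   `n_years`.
#' @export
period_mean_sigma <- function(cube, period) {
  stopifnot(inherits(cube, "yield_cube"))
  sel <- cube$years <= period$start_bp & cube$years > period$end_bp
  if (!any(sel)) {
    abort_fmt("cube has no years inside period '%s' (%d-%d BP)",
              period$name, period$start_bp, period$end_bp)
  }
  slab <- cube$data[, , sel, drop = FALSE]
  n <- dim(slab)[3]
  nr <- dim(slab)[1]; nc <- dim(slab)[2]
  m <- matrix(slab, nr * nc, n)   # rows = cells, cols = years
  mu_v <- rowMeans(m)
  sg_v <- if (n == 1L) mu_v * 0 else sqrt(rowMeans((m - mu_v)^2))
  mu <- matrix(mu_v, nr, nc)
  sg <- matrix(sg_v, nr, nc)
  structure(
    list(
      period = period$name,
      crop_label = cube$crop_label,
      mean = grid_raster(mu, cube$cell_size, cube$origin_x, cube$origin_y,
                         label = sprintf("%s mean %s", cube$crop_label, period$name)),
      sigma = grid_raster(sg, cube$cell_size, cube$origin_x, cube$origin_y,
                          label = sprintf("%s sigma %s", cube$crop_label, period$name)),
      n_years = n
    ),
    class = "period_mean_raster"
  )
}

#' Raster cells inside a circular site catchment
#'
#' Returns the linear indices of all cells whose centres lie within
#' Euclidean distance `radius` of the point `(x, y)` — the
#' centre-in-circle rule. If no centre qualifies (radius small relative
#' to the cell size), the cell containing the point is returned, so the
#' result is never empty: a 200 m catchment stays meaningful on a 300 m
#' yield grid.
#'
#' @param raster A `grid_raster`.
#' @param x,y Site coordinates (m), inside the raster frame.
#' @param radius Catchment radius (m).
#' @return Integer vector of linear (column-major) cell indices, n >= 1.
#' @export
pixels_in_buffer <- function(raster, x, y, radius) {
  stopifnot(inherits(raster, "grid_raster"), radius > 0)
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  home <- cell_at(raster, x, y)   # also validates the point is in frame
  cs <- raster$cell_size
  cc <- cell_centers(raster)
  # candidate window: rows/cols whose centres could be within radius
  span <- ceiling(radius / cs) + 1L
  rows <- max(1L, home[1] - span):min(nr, home[1] + span)
  cols <- max(1L, home[2] - span):min(nc, home[2] + span)
  dx <- cc$x[cols] - x
  dy <- cc$y[rows] - y
  d2 <- outer(dy^2, dx^2, `+`)
  hit <- which(d2 <= radius^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return((home[2] - 1L) * nr + home[1])
  }
  sort((cols[hit[, 2]] - 1L) * nr + rows[hit[, 1]])
}

# Summary statistics for one variable over a set of cells.
# `kind` selects ordinary, circular (aspect) or categorical (soil) handling.
buffer_variable_stats <- function(values, kind = c("numeric", "circular", "categorical")) {
  kind <- match.arg(kind)
  ok <- values[is.finite(values)]
  if (length(ok) == 0L) {
    return(tibble::tibble(stat = "n", value = 0))
  }
  switch(kind,
    numeric = tibble::tibble(
      stat = c("mean", "sd", "median", "n"),
      value = c(mean(ok), if (length(ok) > 1) stats::sd(ok) else 0,
                stats::median(ok), length(ok))
    ),
    circular = tibble::tibble(
      stat = c("mean", "n"),
      value = c(circular_mean_deg(ok), length(ok))
    ),
    categorical = tibble::tibble(
      stat = c("mode", "n"),
      value = c(modal_value(ok), length(ok))
    )
  )
}

#' Circular-buffer catchment summaries for a site table
#'
#' Characterises the immediate catchment of each site by summarising
#' every supplied raster layer over the cells of a circular buffer
#' (centre-in-circle rule, see [pixels_in_buffer()]). Ordinary layers get
#' mean, SD, median and the contributing pixel count; `aspect` uses the
#' circular mean of non-nodata aspects; `soil_class` the modal class with
#' ties broken toward the lowest code. Nodata cells are excluded per
#' variable; a variable with no valid cells in the buffer is reported
#' with `n = 0` and no statistics rather than zeros.
#'
#' @param sites A `site_table` (or data frame with `id`, `x`, `y`).
#' @param layers Named list of aligned `grid_raster`s. Typically a
#'   [terrain_stack()] plus per-period yield `mean`/`sigma` rasters.
#' @param radius Buffer radius, metres.
#' @param period Optional period name recorded in the output.
#' @return A long tibble: `site_id`, `period`, `radius`, `variable`,
#'   `stat`, `value`.
#' @export
summarize_catchments <- function(sites, layers, radius, period = NA_character_) {
  stopifnot(is.data.frame(sites), length(layers) >= 1)
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    abort_fmt("`layers` must be a fully named list of rasters")
  }
  do.call(assert_aligned, unname(layers))
  template <- layers[[1]]
  purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    cells <- pixels_in_buffer(template, sites$x[i], sites$y[i], radius)
    purrr::imap_dfr(layers, function(r, nm) {
      kind <- if (nm == "aspect") "circular"
        else if (nm == "soil_class") "categorical" else "numeric"
      st <- buffer_variable_stats(r$values[cells], kind)
      tibble::tibble(site_id = sites$id[i], period = period,
                     radius = radius, variable = nm,
                     stat = st$stat, value = st$value)
    })
  })
}

#' Per-site catchment means of period-mean yield
#'
#' Convenience reduction used by the landscape comparisons: for each site
#' occupying `period`, the mean of the period-mean yield raster over the
#' site's catchment. One value per site.
#'
#' @param sites A `site_table`.
#' @param pm A `period_mean_raster`.
#' @param radius Buffer radius, metres.
#' @param category Site categories to include (default `"occ_ag"`).
#' @return A tibble `site_id`, `catchment_mean`.
#' @export
catchment_yield_means <- function(sites, pm, radius, category = "occ_ag") {
  stopifnot(inherits(pm, "period_mean_raster"))
  keep <- sites$category %in% category &
    purrr::map_lgl(sites$occupied, ~ pm$period %in% .x)
  sub <- sites[keep, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(tibble::tibble(site_id = character(), catchment_mean = numeric()))
  }
  tibble::tibble(
    site_id = sub$id,
    catchment_mean = vapply(seq_len(nrow(sub)), function(i) {
      cells <- pixels_in_buffer(pm$mean, sub$x[i], sub$y[i], radius)
      v <- pm$mean$values[cells]
      mean(v[is.finite(v)])
    }, numeric(1))
  )
}
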