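#' Planar single-band grid raster
#'
#' `grid_raster()` is the lightweight carrier for every gridded layer the
#' package uses: elevation, slope, terrain ruggedness, distance to water,
#' soil class, and per-period potential-yield surfaces. It is a numeric
#' matrix plus an axis-aligned planar geometry: square cells of `cell_size`
#' metres, row 1 at the north (top) edge, and `origin_x`/`origin_y` the
#' coordinates of the lower-left *corner* of the grid. Nodata cells are
#' stored as `NA`. Coordinates are planar metres in an arbitrary local
#' frame; no geodetic CRS handling is attempted.
#'
#' Two rasters are *aligned* when their shape, cell size, and origin all
#' match. Every cross-raster operation in the package requires alignment and
#' fails loudly on mismatch — nothing is ever silently resampled.
#'
#' @param values Numeric matrix (row 1 = north). `NA` marks nodata.
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin_x,origin_y Planar coordinates (m) of the lower-left corner.
#' @param label Free-text layer description.
#' @return An object of class `grid_raster`.
#' @examples
#' r <- grid_raster(matrix(1:6, 2, 3), cell_size = 100)
#' cell_centers(r)
#' @export
grid_raster <- function(values, cell_size, origin_x = 0, origin_y = 0,
                        label = "") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    abort_fmt("`cell_size` must be a single positive number")
  }
  if (any(is.infinite(values))) {
    abort_fmt("raster values must be finite or NA (nodata)")
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         label = as.character(label)),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<grid_raster> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  %d x %d cells of %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$origin_x, x$origin_y))
  if (length(v)) {
    cat(sprintf("  values: [%g, %g], %d nodata\n", min(v), max(v),
                sum(is.na(x$values))))
  } else {
    cat("  values: all nodata\n")
  }
  invisible(x)
}

#' Test whether rasters share a common grid geometry
#'
#' Alignment is an equivalence relation over shape, cell size and origin.
#'
#' @param a,b `grid_raster` objects.
#' @param ... Further rasters checked against `a`.
#' @return `TRUE` iff all rasters are aligned with `a`.
#' @export
rasters_aligned <- function(a, b, ...) {
  others <- c(list(b), list(...))
  all(vapply(others, function(r) {
    identical(dim(a$values), dim(r$values)) &&
      isTRUE(all.equal(a$cell_size, r$cell_size)) &&
      isTRUE(all.equal(a$origin_x, r$origin_x)) &&
      isTRUE(all.equal(a$origin_y, r$origin_y))
  }, logical(1)))
}

assert_aligned <- function(...) {
  rs <- list(...)
  if (length(rs) > 1 && !do.call(rasters_aligned, rs)) {
    abort_fmt("rasters are not aligned (shape, cell size and origin must match)")
  }
  invisible(TRUE)
}

#' Cell-centre coordinates of a raster
#'
#' @param r A `grid_raster`.
#' @return A list with numeric vectors `x` (per column, west to east) and
#'   `y` (per row, north to south).
#' @export
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(
    x = r$origin_x + (seq_len(nc) - 0.5) * r$cell_size,
    y = r$origin_y + (nr - seq_len(nr) + 0.5) * r$cell_size
  )
}

#' Map a point to the raster cell whose centre is nearest
#'
#' @param r A `grid_raster`.
#' @param x,y Planar point coordinates (m). Must fall inside the grid frame.
#' @return Integer vector `c(row, col)`.
#' @export
cell_at <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  if (x < r$origin_x || x > r$origin_x + nc * r$cell_size ||
      y < r$origin_y || y > r$origin_y + nr * r$cell_size) {
    abort_fmt("point (%g, %g) lies outside the raster frame", x, y)
  }
  col <- min(nc, max(1L, as.integer(floor((x - r$origin_x) / r$cell_size)) + 1L))
  row_from_bottom <- min(nr, max(1L, as.integer(floor((y - r$origin_y) / r$cell_size)) + 1L))
  c(nr - row_from_bottom + 1L, col)
}

#' Tabulate a raster as one row per cell
#'
#' @param x A `grid_raster`.
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `x`, `y`, `value` (nodata rows kept,
#'   `value = NA`).
#' @export
#' @exportS3Method tibble::as_tibble
as_tibble.grid_raster <- function(x, ...) {
  cc <- cell_centers(x)
  nr <- nrow(x$values); nc <- ncol(x$values)
  vals <- as.vector(x$values)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = rep(cc$x, each = nr),
    y = rep(cc$y, times = nc),
    value = vals
  )
}

#' Read and write ESRI ASCII grids
#'
#' The package stores rasters as ESRI ASCII grid files (`.asc`): a
#' six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values, north first. The nodata tag
#' is always written. Values round-trip at full double precision.
#'
#' @param r A `grid_raster` (for writing).
#' @param path File path.
#' @param label Layer label attached on read.
#' @return `read_ascii_grid()` returns a `grid_raster`;
#'   `write_ascii_grid()` invisibly returns `path`.
#' @export
write_ascii_grid <- function(r, path) {
  stopifnot(inherits(r, "grid_raster"))
  v <- r$values
  nodata <- -9999
  if (any(v[!is.na(v)] == nodata)) {
    abort_fmt("raster contains the sentinel value %g; cannot encode nodata", nodata)
  }
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$origin_x),
    sprintf("yllcorner %.10g", r$origin_y),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %g", nodata)
  ), con)
  for (i in seq_len(nrow(v))) {
    writeLines(paste(sprintf("%.17g", v[i, ]), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, label = "") {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && tolower(parts[1]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else {
      break
    }
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  missing <- setdiff(req, names(hdr))
  if (length(missing)) {
    abort_fmt("ASCII grid header missing: %s", paste(missing, collapse = ", "))
  }
  body <- paste(lines[-seq_len(i)], collapse = "\n")
  vals <- scan(text = body, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    abort_fmt("ASCII grid body has %d values, expected %d", length(vals), nr * nc)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  grid_raster(m, cell_size = hdr$cellsize, origin_x = hdr$xllcorner,
              origin_y = hdr$yllcorner, label = label)
}

#' Write a raster to disk and read it back
#'
#' Round-trip helper used to verify that on-disk storage preserves the
#' grid geometry, the values, and the nodata holes exactly.
#'
#' @param r A `grid_raster`.
#' @param path Destination file.
#' @return The re-read `grid_raster`; errors if the result is not aligned
#'   with the input.
#' @export
raster_roundtrip <- function(r, path) {
  write_ascii_grid(r, path)
  back <- read_ascii_grid(path, label = r$label)
  if (!rasters_aligned(r, back)) {
    abort_fmt("round-trip read is not aligned with the written raster")
  }
  back
}
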