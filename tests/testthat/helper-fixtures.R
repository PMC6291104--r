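# Shared fixtures and independent brute-force oracles.
# Oracles are deliberately naive re-computations, kept free of any package
# internals beyond the plain `values` matrices.

tiny_periods <- function() {
  period_table(data.frame(
    name = c("P1", "P2", "P3"),
    start_bp = c(5000, 4300, 3600),
    end_bp = c(4300, 3600, 3000)
  ))
}

# A deterministic site table built directly from per-period occupied/new
# counts: at each period the first (occupied - new) ids of the previous
# period's set persist, the rest are abandoned, and `new` fresh ids join.
build_history <- function(periods, occupied, new, x0 = 0) {
  stopifnot(length(occupied) == nrow(periods), length(new) == length(occupied))
  occ <- list()
  current <- character()
  counter <- 0
  for (t in seq_len(nrow(periods))) {
    keep <- occupied[t] - new[t]
    stopifnot(keep >= 0, keep <= length(current))
    persisting <- current[seq_len(keep)]
    fresh <- if (new[t] > 0) sprintf("site%05d", counter + seq_len(new[t])) else character()
    counter <- counter + new[t]
    current <- c(persisting, fresh)
    for (id in current) occ[[id]] <- c(occ[[id]], periods$name[t])
  }
  ids <- names(occ)
  site_table(tibble::tibble(
    id = ids,
    x = x0 + seq_along(ids),
    y = seq_along(ids),
    category = "occ_ag",
    occupied = unname(occ)
  ), periods)
}

# Central-difference slope/aspect oracle (interior cells only).
oracle_slope_aspect <- function(z, cell) {
  nr <- nrow(z); nc <- ncol(z)
  slope <- matrix(NA_real_, nr, nc); aspect <- matrix(NA_real_, nr, nc)
  for (r in 2:(nr - 1)) {
    for (c in 2:(nc - 1)) {
      dzdx <- (z[r, c + 1] - z[r, c - 1]) / (2 * cell)
      dzdy <- (z[r - 1, c] - z[r + 1, c]) / (2 * cell)
      slope[r, c] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
      aspect[r, c] <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
    }
  }
  list(slope = slope, aspect = aspect)
}

# Direct 8-neighbour TRI oracle with edge padding by replication.
oracle_tri <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      ss <- 0
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- min(nr, max(1, r + dr)); cc <- min(nc, max(1, c + dc))
        ss <- ss + (z[r, c] - z[rr, cc])^2
      }
      out[r, c] <- sqrt(ss)
    }
  }
  out
}

# All-pairs Euclidean distance-to-water oracle over cell centres.
oracle_distance <- function(mask, cell, origin_x = 0, origin_y = 0) {
  nr <- nrow(mask); nc <- ncol(mask)
  cx <- origin_x + (seq_len(nc) - 0.5) * cell
  cy <- origin_y + (nr - seq_len(nr) + 0.5) * cell
  wet <- which(mask == 1, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      out[r, c] <- sqrt(min((cx[c] - cx[wet[, 2]])^2 + (cy[r] - cy[wet[, 1]])^2))
    }
  }
  out
}

# Brute-force centre-in-circle buffer oracle over all cell centres.
oracle_buffer <- function(raster, x, y, radius) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  cc <- cell_centers(raster)
  hits <- integer()
  for (col in seq_len(nc)) {
    for (row in seq_len(nr)) {
      if ((cc$x[col] - x)^2 + (cc$y[row] - y)^2 <= radius^2) {
        hits <- c(hits, (col - 1L) * nr + row)
      }
    }
  }
  sort(hits)
}

# Brute-force D8 contributing-count oracle: follow every cell's flow path
# downstream, counting how often each cell is visited (self included).
oracle_accumulation <- function(z, eps_dir = "west") {
  nr <- nrow(z); nc <- ncol(z)
  eps <- max(diff(range(z)), 1) * 1e-9
  tilt <- switch(eps_dir,
    west = matrix(rep(seq_len(nc) - 1, each = nr), nr, nc),
    east = matrix(rep(nc - seq_len(nc), each = nr), nr, nc))
  zt <- z + eps * tilt
  receiver <- function(r, c) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
    best <- 0; bk <- 0
    for (k in 1:8) {
      rr <- r + dr[k]; cc <- c + dc[k]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      drop <- (zt[r, c] - zt[rr, cc]) / sqrt(dr[k]^2 + dc[k]^2)
      if (drop > best) { best <- drop; bk <- k }
    }
    if (bk == 0) NULL else c(r + dr[bk], c + dc[bk])
  }
  acc <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      pos <- c(r, c)
      repeat {
        acc[pos[1], pos[2]] <- acc[pos[1], pos[2]] + 1
        nxt <- receiver(pos[1], pos[2])
        if (is.null(nxt)) break
        pos <- nxt
      }
    }
  }
  acc
}

# Empirical isotropic variogram by brute force on a value matrix.
oracle_variogram <- function(z, cell, lags) {
  nr <- nrow(z); nc <- ncol(z)
  pts <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  n <- nrow(pts)
  keep <- sample.int(n, min(n, 400))
  pts <- pts[keep, ]
  v <- z[cbind(pts$r, pts$c)]
  d <- as.matrix(dist(cbind(pts$c, pts$r) * cell))
  g <- numeric(length(lags) - 1)
  for (i in seq_along(g)) {
    sel <- d > lags[i] & d <= lags[i + 1]
    g[i] <- mean((outer(v, v, `-`)[sel])^2) / 2
  }
  g
}
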