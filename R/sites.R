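#' Build and validate a site table
#'
#' A site table carries one row per archaeological site: a planar point
#' location, a coarse category — `"occ_ag"` for occupation/agricultural
#' sites (those assumed responsive to agricultural productivity) versus
#' `"other"` — and the set of named periods during which the site was
#' occupied. Occupation sets are validated against a period table: a site
#' citing an unknown period is rejected, as are duplicated ids and empty
#' occupation sets.
#'
#' @param sites A data frame with columns `id`, `x`, `y`, `category`, and
#'   `occupied` (a list-column of character vectors, or a character column
#'   of semicolon-separated period names).
#' @param periods A `period_table` used to validate occupation sets.
#' @return A tibble of class `site_table` with `occupied` as a list-column.
#' @export
site_table <- function(sites, periods) {
  stopifnot(is.data.frame(sites), inherits(periods, "period_table"))
  need <- c("id", "x", "y", "category", "occupied")
  missing <- setdiff(need, names(sites))
  if (length(missing)) {
    abort_fmt("site table is missing column(s): %s", paste(missing, collapse = ", "))
  }
  st <- tibble::as_tibble(sites[need])
  st$id <- as.character(st$id)
  if (anyDuplicated(st$id)) {
    abort_fmt("duplicate site id(s): %s",
              paste(unique(st$id[duplicated(st$id)]), collapse = ", "))
  }
  if (!is.list(st$occupied)) {
    st$occupied <- strsplit(as.character(st$occupied), ";", fixed = TRUE)
  }
  st$occupied <- purrr::map(st$occupied, function(p) trimws(as.character(p)))
  bad_cat <- !st$category %in% c("occ_ag", "other")
  if (any(bad_cat)) {
    abort_fmt("site '%s' has unknown category '%s' (expected occ_ag or other)",
              st$id[which(bad_cat)[1]], st$category[which(bad_cat)[1]])
  }
  for (i in seq_len(nrow(st))) {
    occ <- st$occupied[[i]]
    if (length(occ) == 0L || all(!nzchar(occ))) {
      abort_fmt("site '%s' has an empty occupation set", st$id[i])
    }
    unknown <- setdiff(occ, periods$name)
    if (length(unknown)) {
      abort_fmt("site '%s' cites unknown period(s): %s", st$id[i],
                paste(unknown, collapse = ", "))
    }
  }
  class(st) <- c("site_table", class(st))
  st
}

#' Read or write a site table as CSV
#'
#' The on-disk form is a plain CSV with columns `id`, `x`, `y`,
#' `category`, `occupied`, the latter holding semicolon-separated period
#' names. Loading validates every record against the period table.
#'
#' @param path File path.
#' @param periods A `period_table`.
#' @param sites A `site_table` (for writing).
#' @return `load_sites()` returns a validated `site_table`.
#' @export
load_sites <- function(path, periods) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_guess()))
  need <- c("id", "x", "y", "category", "occupied")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort_fmt("site file '%s' is missing column(s): %s", path,
              paste(missing, collapse = ", "))
  }
  df$occupied <- as.character(df$occupied)
  site_table(df, periods)
}

#' @rdname load_sites
#' @export
write_sites <- function(sites, path) {
  stopifnot(inherits(sites, "site_table"))
  out <- tibble::as_tibble(sites)
  out$occupied <- vapply(out$occupied, paste, character(1), collapse = ";")
  readr::write_csv(out, path)
  invisible(path)
}

# occ_ag site ids occupied during a named period
occ_ag_ids <- function(sites, period_name) {
  keep <- sites$category == "occ_ag" &
    purrr::map_lgl(sites$occupied, ~ period_name %in% .x)
  sites$id[keep]
}
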