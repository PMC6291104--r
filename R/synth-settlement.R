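#' Generate a settlement history with productivity preference
#'
#' Simulates per-period site sets over a landscape whose locational
#' preference for potential agricultural productivity (PAgP) varies in
#' sign and strength between periods. For each period, in chronological
#' order: sites occupied in the previous period persist with probability
#' `p_persist`; additional sites are then founded, without replacement, on
#' unoccupied land cells with probability proportional to
#' `exp(beta * z)`, where `z` is the standardised period-mean PAgP of the
#' cell, until the period's `n_sites` target is reached. `beta = 0` is
#' uniform placement; positive `beta` concentrates settlement on
#' productive land, negative `beta` avoids it. Each new site is classed
#' `occ_ag` with probability `frac_occ_ag`, `other` otherwise, at
#' foundation and keeps that category for life. Occupation sets accumulate
#' across periods.
#'
#' The preference model is an artifact of the generator, chosen for
#' parameter recoverability by the downstream comparisons; it is not an
#' empirical settlement-choice model.
#'
#' @param seed Integer RNG seed.
#' @param scenario A data frame, one row per period in order, with columns
#'   `period`, `n_sites`, `beta`, `p_persist`, `frac_occ_ag`.
#' @param period_means Named list of aligned `grid_raster`s of period-mean
#'   PAgP, names covering every scenario period.
#' @param periods A `period_table`; scenario periods must appear in it.
#' @return A `site_table` with sites located at cell centres.
#' @examples
#' dem <- gen_dem(1, 20, 20, relief_amplitude = 0)
#' pm <- grid_raster(matrix(runif(400), 20), 300, label = "pagp")
#' pt <- period_table(data.frame(name = "A", start_bp = 4000, end_bp = 3500))
#' sc <- data.frame(period = "A", n_sites = 30, beta = 1,
#'                  p_persist = 1, frac_occ_ag = 1)
#' gen_settlement_history(7, sc, list(A = pm), pt)
#' @export
gen_settlement_history <- function(seed, scenario, period_means, periods) {
  stopifnot(is.data.frame(scenario), inherits(periods, "period_table"))
  need <- c("period", "n_sites", "beta", "p_persist", "frac_occ_ag")
  missing <- setdiff(need, names(scenario))
  if (length(missing)) {
    abort_fmt("scenario is missing column(s): %s", paste(missing, collapse = ", "))
  }
  unknown <- setdiff(scenario$period, periods$name)
  if (length(unknown)) {
    abort_fmt("scenario period(s) not in the period table: %s",
              paste(unknown, collapse = ", "))
  }
  if (any(scenario$n_sites < 0) || any(scenario$p_persist < 0) ||
      any(scenario$p_persist > 1)) {
    abort_fmt("scenario requires n_sites >= 0 and p_persist in [0, 1]")
  }
  template <- period_means[[scenario$period[1]]]
  for (p in scenario$period) {
    if (is.null(period_means[[p]])) {
      abort_fmt("period_means is missing period '%s'", p)
    }
    assert_aligned(template, period_means[[p]])
  }

  nr <- nrow(template$values)
  cc <- cell_centers(template)
  registry <- tibble::tibble(id = character(), cell = integer(),
                             category = character())
  occupation <- list()   # id -> character vector of periods
  prev_ids <- character()
  counter <- 0L

  with_seed(seed, {
    for (i in seq_len(nrow(scenario))) {
      pname <- scenario$period[i]
      pm <- period_means[[pname]]$values
      land <- which(!is.na(pm))

      persisting <- prev_ids[stats::runif(length(prev_ids)) <=
                               scenario$p_persist[i]]
      for (id in persisting) occupation[[id]] <- c(occupation[[id]], pname)

      n_new <- max(0L, scenario$n_sites[i] - length(persisting))
      active_cells <- registry$cell[registry$id %in% persisting]
      free <- setdiff(land, active_cells)
      if (n_new > length(free)) {
        abort_fmt("period '%s' needs %d new sites but only %d free land cells",
                  pname, n_new, length(free))
      }
      if (n_new > 0L) {
        z <- pm[free]
        z <- if (stats::sd(pm[land]) > 0) {
          (z - mean(pm[land])) / stats::sd(pm[land])
        } else {
          rep(0, length(free))
        }
        w <- exp(scenario$beta[i] * z)
        chosen <- if (n_new == length(free)) free else
          sample(free, n_new, prob = w)
        cats <- ifelse(stats::runif(n_new) <= scenario$frac_occ_ag[i],
                       "occ_ag", "other")
        ids <- sprintf("s%05d", counter + seq_len(n_new))
        counter <- counter + n_new
        registry <- dplyr::bind_rows(registry, tibble::tibble(
          id = ids, cell = chosen, category = cats))
        for (k in seq_along(ids)) occupation[[ids[k]]] <- pname
        prev_ids <- c(persisting, ids)
      } else {
        prev_ids <- persisting
      }
    }
  })

  if (nrow(registry) == 0L) {
    abort_fmt("scenario generated no sites")
  }
  registry$x <- cc$x[(registry$cell - 1L) %/% nr + 1L]
  registry$y <- cc$y[(registry$cell - 1L) %% nr + 1L]
  registry$occupied <- unname(occupation[registry$id])
  site_table(registry[c("id", "x", "y", "category", "occupied")], periods)
}
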