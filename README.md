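# paleocatch

Site-catchment analysis of diachronic settlement patterns against
potential agricultural productivity (PAgP).

## The problem

Archaeologists asking whether past climate change mattered to the people
who lived through it need more than a correlation between a proxy curve
and a culture-historical phase. One productive approach is to convert
climate into a variable people actually experienced — the potential
yield of their fields, in tonnes of fresh matter per hectare (tFM/ha) —
and then ask, period by period, whether settlements sat on land that was
more productive than the landscape offered at random, and whether that
preference tracked or ignored climate-driven swings in productivity.

`paleocatch` implements that workflow for gridded yield reconstructions
and point inventories of archaeological sites:

- **Site catchments.** Each occupation/agricultural site is
  characterised by the raster cells within a circular buffer (200 m by
  default, a 12.6 ha catchment), summarising terrain covariates
  (elevation, slope, aspect, terrain ruggedness, distance to fresh
  water, soil class) and per-period mean and σ of potential yield.
- **Landscape vs. exploited fraction.** For every period the
  distribution of catchment-mean yields (the *exploited fraction*) is
  compared with the distribution over all landscape cells: medians,
  midspreads (Q1–Q3), percentile-bootstrap 95% CIs of the median, a
  centennial difference series, and permutation tests on group means.
- **Transition bookkeeping.** Per-period counts of occupied, newly
  established and abandoned sites obeying
  `occupied(t) = occupied(t-1) - abandoned(t) + new(t)`, with
  time-standardised counts (`count * min_length / length`, rounded
  half-up) and multiplicative taphonomic corrections.
- **Intensity regression.** Settlement intensity (sites/km²) regressed
  on binned yield (0.1 tFM/ha bins), area-weighted by default, plus a
  subsistence diagnostic: the landscape fraction below ~1.0 tFM/ha.
- **Synthetic data.** Because regional site inventories and
  paleo-yield rasters are typically restricted, the package ships a
  generator for every input: spectral-synthesis fractal terrain, D8
  watercourses, centennial climate with step events, a declared
  surrogate yield response (two intensity registers W1/W2), and
  settlement histories with a tunable productivity preference `beta`.
  Every downstream statistic is therefore testable end to end with
  known ground truth.

Everything user-facing takes and returns tibbles, composes with the
pipe, and has `tidy()`/`glance()`/`autoplot()` methods where a model
object is involved.

## Worked example

The bundled Provence chronology and published per-period counts
(`provence_periods()`, `provence_counts()`) feed the count machinery
directly:

```r
library(paleocatch)

pc <- provence_counts()
chronology_report(pc[c("period", "total_sites", "occ_ag", "new", "abandoned")],
                  provence_periods(),
                  setNames(pc$taphonomy_factor, pc$period))
#>    period         occ_ag   new abandoned length time_adjusted taphonomy_adjusted
#>  1 Early Neolith…    125   125         0    500            75               5898
#>  2 Middle Neolit…    125     0         0    600            63               3438
#>  3 Late Neolithic    131     7         1    800            49               2092
#>  4 Final Neolith…    147    22         6   1400            32               2348
#>  5 Early Bronze …    147     0         0    800            55               3715
#>  6 Middle Bronze…     23     0       124    300            23                581
#>  7 Late Bronze A…     52    32         3    450            35               1314
#>  8 Early Iron Age     57     5         0    300            57                553
#>  9 Late Iron Age     409   365        13    398           308               3967
#> 10 Gallo-Roman       432    24         1    552           235               3737
```

The Middle Bronze Age row is the famous signal: 124 of 147 sites
abandoned, and a time-standardised count collapsing from 55 to 23.

A fully synthetic comparison, from terrain to statistics:

```r
dem     <- gen_dem(42, 40, 40, cell_size = 300, relief_amplitude = 700)
slope   <- slope_aspect(dem)$slope
soil    <- gen_soil(43, dem, 3)
climate <- gen_climate_series(44, 5000, 3500,
             events = data.frame(start_bp = 4200, end_bp = 4000,
                                 precip_multiplier = 0.8))
cube    <- gen_yield_cube(45, dem, slope, soil, c("1"=1, "2"=0.85, "3"=0.7),
                          climate, "W1", annual_noise_sd = 0.1)

pt <- period_table(data.frame(name = c("Occupation", "Decline"),
                              start_bp = c(5000, 4300), end_bp = c(4300, 3600)))
pm <- period_mean_sigma(cube, pt[1, ])

scenario <- data.frame(period = pt$name, n_sites = c(120, 40),
                       beta = c(1.5, -1.5), p_persist = c(1, 0.25),
                       frac_occ_ag = 1)
pms   <- list(Occupation = pm$mean,
              Decline = period_mean_sigma(cube, pt[2, ])$mean)
sites <- gen_settlement_history(46, scenario, pms, pt)

cm <- catchment_yield_means(sites, pm, radius = 200)
tidy(exploited_vs_landscape(pm, cm, seed = 1))
#>   source        n median    q1    q3 ci_low ci_high period     crop_label
#> 1 landscape  1600  0.958 0.776  1.15  0.944   0.976 Occupation W1
#> 2 exploited   120  1.30  1.13   1.42  1.26    1.34  Occupation W1

glance(binned_intensity_regression(pm, cm, bin_width = 0.1))
#>   period     crop_label slope intercept r_squared weighted defined n_bins n_sites
#> 1 Occupation W1          3.67     -2.66     0.549 TRUE     TRUE        18     120

subsistence_fraction(pm)
#> [1] 0.562
```

With `beta = +1.5` the generator planted a preference for productive
land, and the comparison recovers it: the exploited-fraction median
(1.30 tFM/ha) sits above the landscape third quartile, and intensity
rises by ~3.7 sites/km² per tFM/ha. In this mid-Holocene synthetic
landscape, 56% of cells fall below the ~1.0 tFM/ha subsistence
threshold under the high-intensity register — location choice matters.

The whole pipeline (simulation → terrain → summaries → catchments →
counts → comparisons → regression, with a JSON manifest) runs as one
call, or from a shell:

```sh
Rscript inst/scripts/run_pipeline.R --out runs/demo --seed 42
```

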