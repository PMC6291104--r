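---
title: "Methods: site catchments, yield surfaces, and the statistics behind them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: site catchments, yield surfaces, and the statistics behind them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleocatch)
```

This vignette is the package's own account of its methods: the model
behind each stage, the parameters that matter, the numerical decisions
taken where the field offers no single convention, and what the
synthetic-data generator can and cannot tell you about real data.

## 1. The analytical frame

The package operationalises a simple question — *did settlement
location track potential agricultural productivity (PAgP), period by
period?* — as a comparison between two distributions per archaeological
period:

- the **landscape**: per-pixel mean yield over the period's years,
  summarised over every non-nodata cell;
- the **exploited fraction**: the same raster summarised within a
  circular catchment around each occupation/agricultural site, one
  catchment-mean value per site.

Both sides are reduced to a median, a midspread (Q1–Q3), and a 95%
confidence interval of the median. The exploited-minus-landscape median
difference, tracked century by century, is the primary diachronic
signal; a positive difference means inhabitants sat on
better-than-random land.

All coordinates are planar metres in a local frame. Rasters are plain
matrices with square cells and an explicit nodata code, stored on disk
as ESRI ASCII grids; alignment (shape, cell size, origin) is checked on
every cross-raster operation and nothing is ever resampled silently.

## 2. Site catchments

A catchment is the set of cells whose *centres* fall within radius
`r` of the site (`pixels_in_buffer()`). Centre-in-circle membership,
rather than area-weighted intersection, keeps the operation exactly
reproducible and trivially checkable against a brute-force scan of all
cell centres; at the default 200 m radius on a 30 m terrain grid the
catchment holds ~140 cells (12.6 ha), so partial-cell effects are
second order. Two guarantees matter downstream:

- **Never empty.** On a coarse grid (300 m yield cells) a 200 m circle
  can miss every centre; the cell containing the site is then returned,
  so a catchment mean always exists.
- **Radius-monotone and translation-invariant.** `r1 <= r2` implies the
  smaller set is contained in the larger; shifting the grid origin
  changes nothing.

Catchment summaries report mean, SD, median and the contributing pixel
count per variable, excluding nodata per variable; a variable with no
valid cells is reported with `n = 0`, never as a fabricated zero.
Aspect is averaged on the circle (circular mean of angles); soil class
takes the modal code, ties broken toward the lowest code so results
never depend on traversal order.

The default radii are 200, 500 and 1000 m with 200 m as the headline
radius; the larger radii are computed for sensitivity only, since
catchment summaries change little with buffer size relative to the
between-period signal.

## 3. Terrain covariates

Slope and aspect use Horn's 8-neighbour weighted differences — the de
facto standard for gridded elevation models — with slope in degrees and
aspect the downslope azimuth clockwise from north, nodata where the
gradient is exactly zero (a flat cell has no meaningful aspect). The
terrain ruggedness index is the Riley formulation: the root of summed
squared differences to the eight neighbours. Edge cells replicate their
nearest neighbour. Distance to fresh water is the exact straight-line
distance between cell centres: no cost surface or flow routing is
assumed because the analysis makes no transport claims.

## 4. The yield surrogate

Process-based agro-ecosystem models are the right tool for
reconstructing attainable yields, but they are external infrastructure.
The package's generator therefore uses an explicit *surrogate* — a
separable response surface that reproduces only the structure the
downstream statistics consume:

$$Y = Y_{max}\; \mathrm{tri}(T;\,T_{min},T_{opt},T_{max})\;
  \frac{P}{P + P_{1/2}}\;
  \max\!\big(0,\, 1 - \max(0, s - s_{knee})\, r_s\big)\; f_{soil}$$

with `tri()` a triangular temperature response, a saturating
(Michaelis-type) water response — chosen over a linear ramp so step
events in precipitation do not produce yield cliffs — a linear slope
penalty beyond a 5° knee, and a soil multiplier. Temperature is lapsed
with elevation at 6.5 °C/km, which couples yield to terrain and gives
the landscape its spatial heterogeneity.

The registered crop labels are two wheat intensity registers, W1
(`Ymax` 2.5 tFM/ha, maximally intensive preindustrial management) and
W2 (`Ymax` 0.9, minimally intensive), plus analogous pulse labels
P1/P2. Within a crop the two registers share every response parameter
and differ *only* in `Ymax`: the intensification gap is a pure scaling,
so the W1/W2 ratio is algebraically exact and the gap (~2.8×) dwarfs
climate-driven swings (a −20% precipitation event moves landscape
median yield by roughly 5–8% at the default `P_half` = 250 mm). That
ordering — management margin ≫ climate margin — is the qualitative
relationship the comparisons are designed to probe. At the default
baseline (13 °C, 700 mm/yr) W1 yields ≈ 1.7 tFM/ha on flat good soil,
a plausible preindustrial magnitude.

Interannual noise is lognormal with mean exactly 1 and coefficient of
variation `annual_noise_sd` (the log-scale parameters are solved from
those moments, not approximated). Under a common seed the same noise
realisation is applied to every crop label, keeping register ratios
noise-free.

## 5. The synthetic landscape and settlement process

- **Terrain** is spectral-synthesis fractal noise (power-law filtered
  white noise, exponent `roughness` = 1.6), rescaled to a stated total
  relief — 800 m over a 125 × 125 grid of 300 m cells (~1400 km²) by
  default, a deliberately mountainous-Mediterranean scale.
- **Watercourses** come from D8 steepest-descent routing with
  contributing-cell counts; flats are resolved by an infinitesimal tilt
  toward the lowest frame edge (ties broken west, east, south, north),
  so even a perfectly flat surface has a defined, documented drainage.
- **Climate** is centennial: baseline + linear trend + AR(1) noise,
  with multiplicative precipitation events and additive temperature
  shifts over closed windows; the bundled default is a −20%
  precipitation step over 4200–4000 BP inside an 8400–1400 BP span.
- **Settlement** follows a per-period scenario: sites persist with
  probability `p_persist`, and new sites are drawn without replacement
  from unoccupied land cells with probability ∝ `exp(beta * z)`, `z`
  the standardised period-mean yield. `beta` is an artifact of the
  generator — a dial for planting a known preference, not an empirical
  settlement-choice model. The default trajectory (positive `beta`
  through the Neolithic/Early Bronze Age, negative for Middle Bronze
  through Early Iron Age, strongly positive after) reproduces the
  qualitative pattern the statistics must detect, with per-period site
  targets and persistence rates taken from the published regional
  counts bundled as `provence_counts()`.

What the generator does **not** emulate: spatially correlated discovery
/ preservation bias (taphonomy enters only as external multiplicative
factors), site-size hierarchies, multi-crop rotation, soil genesis, and
any feedback of settlement on the landscape. A passing test suite
therefore demonstrates that the statistics recover planted structure
under clean sampling — not that real inventories are unbiased.

## 6. Statistical machinery

**Quantiles and CIs.** Medians and quartiles use linear-interpolation
quantiles (R type 7). The CI of the median is a percentile bootstrap
(default 1000 resamples, fixed seed; all bootstrap and permutation
routines are seed-deterministic). For landscape summaries the bootstrap
treats pixels as independent, which spatial autocorrelation makes
anti-conservative — the landscape CIs are best read as lower bounds on
uncertainty. Calibration on independent draws is part of the test
suite: coverage of the median CI is required to sit within 95% ± 3%
over 400 replicates.

**Group comparisons.** Differences between periods, or between the
exploited fraction and the landscape, use a two-sided permutation test
on the difference of means — chosen as the distribution-free option
when no test is otherwise specified. When `choose(nA+nB, nA)` ≤ 20,000
the null is enumerated exactly; otherwise Monte-Carlo permutations are
drawn and the p-value includes the observed statistic (add-one), which
keeps the test valid (type-I error at α = 0.05 is required to lie in
[0.03, 0.07] over 1000 null simulations). Pairwise period grids are
reported as raw p-values; no multiplicity correction is applied, and
users scanning many contrasts should apply their own.

**Intensity regression.** The landscape is binned by period-mean yield
(0.1 tFM/ha bins from zero); each site falls in the bin of its
catchment-mean yield (the single-pixel-at-site alternative is available
by passing those values instead); intensity = sites/km² per bin. The
least-squares fit of intensity on bin midpoints is area-weighted by
default — unweighted fits let near-empty marginal bins dominate — with
an unweighted switch, and both report slope, intercept and R². Fewer
than two nonempty bins yields an explicitly undefined fit.

**Difference series.** Centennial steps; a century on a period boundary
belongs to the older period (BP convention throughout: larger = older).
The series is a step function at period boundaries by construction,
because the site set changes only with the period.

**Counts.** Time-standardised counts divide by period length in units
of the shortest period; taphonomic corrections multiply by external
factors. Both round half-up (31.5 → 32, 5897.5 → 5898) — the only rule
consistent with the published adjusted tables the package bundles — and
are idempotent at factor 1. The report recomputes the bookkeeping
identity and flags, rather than repairs, any inconsistency in supplied
counts. Only the occupation/agricultural adjusted column is recomputed;
published *total*-site adjusted columns do not follow a stated rule and
are not guessed at.

**Landscape register.** Where a period-level landscape summary is
needed, the default summarises the per-period mean raster; summarising
pooled centennial rasters within the period is available via
`difference_series()`, which computes per-century landscape medians.

## 7. Degenerate inputs and tie-breaks, collected

- Alignment failure on any cross-raster operation is an error, never a
  resample. Nodata propagates through temporal reductions.
- `n = 1` distribution summaries return all statistics equal;
  zero-site periods return the landscape side only, with the exploited
  side marked absent.
- Flat DEM: slope 0, aspect nodata, ruggedness 0, drainage via the
  epsilon tilt; relief amplitude 0 is an exactly flat raster.
- Soil-mode ties go to the lowest class code; period-boundary centuries
  to the older period; D8 ties to the first neighbour in a fixed
  compass order.
- Temporal σ per pixel is the population SD (divide by n), documented
  so closed-form checks are exact.
- Negative precipitation after event application is clipped to zero
  with a warning.

## 8. Problem sizes in the test suite

The suite exercises the full pipeline at reduced scale so the whole run
stays interactive: oracle comparisons on grids of at most 12 × 12
against brute-force reimplementations (exact for ruggedness, distance
and zonal means; 1.5° for slope on smooth random surfaces — white-noise
terrain is deliberately avoided as a fixture because aspect is
ill-conditioned on near-flat cells); preference recovery with 200 sites
on 45 × 45 landscapes over 20 replicate seeds and `beta` ∈ {−2…2};
permutation calibration over 1000 null datasets; bootstrap coverage
over 400 replicates; and an end-to-end pipeline determinism check on a
20 × 20 landscape (reruns must be byte-identical). The bundled default
simulation (125 × 125, 71 centennial steps, two crops) is sized for a
single-CPU run of a few minutes.

## 9. Known limitations

- The surrogate is not a crop model; only contrasts *within* a
  parameterisation are meaningful, never absolute yields.
- Pixel-independence in the landscape bootstrap (see above).
- Straight-line water distance ignores terrain cost.
- The settlement generator's `beta` is a testing construct; fitted
  slopes from real data should be interpreted through the regression
  module's assumptions, not through `beta`.
- Modern terrain and hydrology stand in for past landscapes; no
  erosion retrodiction or paleo-vegetation reconstruction is attempted.
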