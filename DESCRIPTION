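Package: paleocatch
Title: Site-Catchment Analysis of Settlement Patterns Against Potential
    Agricultural Productivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating diachronic archaeological settlement
    patterns to spatially and temporally variable potential agricultural
    productivity (PAgP). Implements circular-buffer site-catchment
    summaries over terrain and yield rasters, landscape versus
    exploited-fraction distribution comparisons with bootstrap confidence
    intervals and permutation tests, period-transition bookkeeping with
    time-standardised and taphonomic count adjustments, binned
    settlement-intensity regression, and a synthetic-data generator
    (fractal terrain, centennial climate with step events, a
    climate-driven crop-yield surrogate, and preference-driven settlement
    histories) so the full pipeline is testable without restricted
    archaeological inventories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
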