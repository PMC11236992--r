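Package: thermoshift
Title: Thermophilization Analysis of Repeated Forest Inventories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify thermophilization - the directional shift of
    tree communities towards species affiliated with warmer climates - from
    repeated forest inventory censuses. Derives species thermal and
    precipitation optima from cleaned, grid-deduplicated occurrence records
    scored against a gridded climatology; computes stem-abundance and
    basal-area weighted community temperature and precipitation indices
    (CTI/CPI) and their annual rates of change; partitions index change
    additively into recruitment, mortality and growth components; quantifies
    per-species contributions by jackknife; and estimates aboveground carbon
    stocks and census-interval-corrected gain and loss fluxes from
    diameter-height-wood-density allometry. Includes a stem-level demographic
    simulator with known thermal biases so every stage of the pipeline can be
    validated by parameter recovery, and a statistical layer (one-sample
    Wilcoxon tests, bootstrap confidence intervals, rank correlations,
    climate trend slopes) mirroring standard practice in plot-network
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
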