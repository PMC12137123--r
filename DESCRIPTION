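Package: trackrec
Title: Seabed Mining-Track Disturbance and Recovery Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the seafloor footprint of a nodule-collector
    test and the state of the benthic system decades later. Includes a
    moving-source turbidity-current box model for near-field sediment plume
    deposition, moving-window micro-relief statistics for centimetre-scale
    digital terrain models with a subsample-maximum procedure, photo-transect
    megafauna density estimation with explicit fixed-area sample units,
    phospholipid fatty acid (PLFA) biomass and 13C pulse-chase assimilation
    conversions, nodule abundance metrics, self-contained non-parametric group
    comparisons (Kruskal-Wallis, rank-sum, Holm), and a deterministic synthetic
    data generator so the full pipeline runs without external downloads.
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
    utils,
    withr
Suggests:
    deSolve,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
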