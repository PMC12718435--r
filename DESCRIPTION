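Package: diatomtf
Title: Diatom-Environment Calibration and Transfer Functions for Coastal
    Training Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for building and stress-testing
    species-environment calibration (transfer-function) models from coastal
    diatom training sets. Covers preprocessing of valve-count and water
    chemistry tables (rare-taxon filtering, Hellinger transformation,
    skewness-guided log transforms), environmental-variable screening by
    correlation grouping, redundancy analysis with Monte Carlo permutation
    tests, forward selection, independence testing and the eigenvalue-ratio
    criterion, weighted-averaging and weighted-averaging partial least
    squares (WAPLS) calibration with inverse/classical deshrinking and
    tolerance down-weighting, leave-one-out validation with RMSEP and
    segment-wise maximum bias, random/neighbor/environment (RNE) deletion
    diagnostics for spatial autocorrelation, indicator-species analysis,
    hierarchical clustering, and a seeded synthetic generator of
    gradient-structured community data with known taxon optima for
    method-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    e1071,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
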