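Package: pbcnet
Title: Phylogenetic Biogeographic Connectedness and Fossil Sampling-Bias Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies faunal provincialism versus cosmopolitanism in fossil
    assemblages with phylogenetically corrected Biogeographic Connectedness
    (pBC), a network statistic on taxon-by-region occupancy weighted by
    patristic distance on time-calibrated phylogenies. Provides
    minimum-branch-length time-scaling of fossil trees, jackknife,
    rarefaction and permutation-null resampling of the statistic, a
    latitudinal subsampling experiment, latitudinal occurrence/collection
    binning with rank correlations, generalized least-squares regression
    with first-order autoregressive errors and AICc-based model selection
    over sampling-bias covariates, and a synthetic-data generator with
    known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nlme,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
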