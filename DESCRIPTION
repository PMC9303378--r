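Package: rrasweep
Title: Abundance-Threshold Sweeps, Hill Numbers and Richness Extrapolation
    for Dietary DNA Metabarcoding
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how sample-wise relative read abundance (RRA)
    thresholds distort dietary DNA metabarcoding profiles. Provides a
    Pareto-style rank-abundance diet simulator for specialist, intermediate
    and generalist consumers, a threshold-sweep engine measuring richness
    loss, convergence and rank-order inversion, taxon dropout ledgers,
    Hill-number diversity profiles over the order q, read-depth rarefaction,
    incidence-based (Chao2) richness estimation with extrapolation and
    bootstrap confidence intervals, and a synthetic generator emulating a
    two-species, two-season herbivore fecal data set with partially
    annotated plant taxonomy and a companion microhistology table.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
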