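Package: mrfmap
Title: Magnetic Resonance Fingerprinting Simulation, Dictionary Matching
    and Repeatability Statistics
Version: 0.1.0
Authors@R:
    person("Alex", "Morland", email = "alex.morland@example.org",
           role = c("aut", "cre"))
Description: Simulation and quantification chain for inversion-prepared
    FISP magnetic resonance fingerprinting (MRF). Provides an extended
    phase graph (EPG) signal simulator for gradient-spoiled echo trains,
    dictionary generation on multi-resolution (T1, T2, B1) grids with SVD
    temporal compression, B1-informed inner-product dictionary matching
    with low-T1 masking, gold-standard inversion-recovery T1 and
    spin-echo T2 reference fitting, digital phantom and brain-like
    synthetic data generators, and the quality-assurance statistics used
    to validate quantitative MRI systems (test-retest variation,
    longitudinal coefficient of variation, percent deviation from NMR
    reference, Bland-Altman agreement, region summaries and age-trend
    fits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
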