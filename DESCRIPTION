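Package: pdcnet
Title: Directed Functional Connectivity Classification with Weighted
    Partial Directed Coherence and Balanced Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of directed functional connectivity in
    multichannel neural time series. Generates cohorts of subjects whose
    region-of-interest signals follow stable multivariate autoregressive
    (MVAR) processes with group-specific directed couplings, estimates
    directed connectivity per epoch with weighted partial directed coherence
    (wPDC) reduced to theta/alpha/beta band means, and evaluates a sequential
    two-stage classification system (diagnosis, then lateralization) built on
    balanced random forests with permutation-importance feature selection,
    pairwise feature-interaction effects, and leave-one-out cross-validation
    with per-fold selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ranger,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'pdcnet-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'bands.R'
    'mvar.R'
    'pdc.R'
    'features.R'
    'forest.R'
    'importance.R'
    'selection.R'
    'interaction.R'
    'classify.R'
    'template.R'
    'cohort.R'
    'io.R'
    'pipeline.R'
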