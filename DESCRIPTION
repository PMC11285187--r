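Package: gmnets
Title: Longitudinal Grey-Matter Network Measures for Clinical Trials
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers networks of co-varying regional grey-matter volumes in
    longitudinal cohorts by spatial independent component analysis, trains a
    sparse (Lasso) surrogate model so the network measures can be computed
    prospectively on unseen participants and visits, harmonizes measures
    across scanners and sites with empirical-Bayes location/scale (ComBat)
    adjustment, and runs the longitudinal statistical battery used in
    multiple sclerosis trial analyses: phenotype trajectory contrasts,
    disability (EDSS) associations, stepwise predictor selection, treatment
    effect detection, first-to-last-visit effect sizes and per-arm sample
    size estimation. Includes a synthetic-cohort generator with planted
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    lme4,
    Matrix,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
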