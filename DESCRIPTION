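Package: spiropatch
Title: Spirometry Estimation from Wearable Tracheal Sound and Chest Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for wearable digital-spirometry recordings:
    respiratory phase detection from tracheal sound energy and chest
    accelerometry, per-breath acoustic (MFCC) and kinematic feature
    extraction, Boruta shadow-feature screening, and elastic-net estimation
    of FVC, FEV1 and PEF under leave-one-subject-out cross-validation, with
    subject-level error aggregation and a random-intercept mixed-model
    comparison of breathing modes. Includes a synthetic-data module that
    emulates multimodal patch recordings and cohorts with known ground
    truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    ranger,
    lme4,
    ggplot2,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
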