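Package: ginscreen
Title: Graph Isomorphism Network Screening of Acute Suicidal Ideation
    from Multi-Dimensional Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds per-subject psychometric graphs from depression,
    anxiety, resilience and self-esteem questionnaire items via a shared
    thresholded correlation edge matrix, classifies them with a graph
    isomorphism network (GIN), corrects extreme class imbalance with an
    under-sampling/SMOTE-NC soft-voting ensemble, pseudo-labels major
    depressive episodes for use as an input node, and interprets the
    fitted ensemble with input-gradient attention plots.  Includes a
    synthetic cohort generator with planted, recoverable effects, DeLong
    ROC comparisons, Steiger dependent-correlation tests, and penalized
    logistic / support-vector baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    glmnet,
    e1071,
    yaml,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
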