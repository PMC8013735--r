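Package: dfcstates
Title: Dynamic Functional Connectivity States, Transition Features and
    Group Discrimination for Resting-State Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for dynamic functional connectivity (dFC) analysis of
    network node time courses: tapered sliding-window covariance, k-means
    decomposition of windowed connectivity into recurring brain states with
    elbow-based model selection, per-subject Markov state-transition
    probability features, elastic-net logistic regression for group
    discrimination with regularization-path feature-retention importance,
    and covariate-adjusted partial-correlation association between
    transition features and symptom scores with Benjamini-Hochberg FDR
    control. Includes a hidden-Markov covariance-switching cohort simulator
    with plantable group contrasts and symptom couplings so every stage is
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    MASS,
    glmnet,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
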