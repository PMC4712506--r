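Package: subtyperefine
Title: Iterative Ensemble-Consensus Refinement of Intrinsic Subtype Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iteratively refines per-sample molecular subtype labels for
    gene expression cohorts. Each pass scores every probe's discriminative
    power for every class with the signed CM1 statistic, selects per-class
    up- and down-regulated feature sets, trains a declared roster of
    heterogeneous classifiers on class-balanced subsamples under stratified
    cross-validation, and relabels samples by vote consensus, marking
    low-agreement samples inconsistent. Stopping combines label/feature
    stability with a Fleiss' kappa criterion. Includes a two-stage
    discovery/validation workflow, first-principles agreement statistics
    (Cramer's V, Fleiss' kappa, adjusted Rand index), Kaplan-Meier and
    log-rank survival stratification, clinical marker summaries, and a
    seed-deterministic synthetic data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    withr,
    rpart,
    tree,
    nnet,
    e1071,
    MASS,
    class,
    ranger,
    xgboost,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    survival,
    yaml
Config/testthat/edition: 3
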