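Package: mirvote
Title: Ensemble-Vote Classification of Recurrence Risk from miRNA Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns lymph-node-negative breast-cancer patients to
    ultralow-, low- and high-risk recurrence groups from tumor microRNA
    expression. Implements pair-matched leave-one-pair-out cross-validation
    with per-fold FDR-controlled feature selection, an ensemble of seven
    voting classifiers (radial and linear SVM, random forest, naive Bayes,
    Cox risk-sum, k-nearest neighbors, ridge logistic regression), vote
    aggregation under fixed or dataset-adaptive cutoffs, external-cohort
    transfer with feature harmonization, and the associated evaluation
    statistics (exact one-tailed Fisher tests, Kaplan-Meier curves, Cox
    hazard ratios, multivariable logistic independence checks). Includes a
    synthetic matched case-control cohort generator with planted
    differential miRNAs and survival structure so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    FNN,
    quadprog,
    truncnorm,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
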