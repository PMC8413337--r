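Package: targetDDI
Title: Drug-Drug Interaction Prediction from Drug Target Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts drug-drug interactions from drug target-gene profiles.
    Drug pairs are represented by the elementwise sum of the two drugs' binary
    target-profile vectors over a fixed gene universe and classified with an
    l2-regularized logistic regression model. Companion statistics quantify
    the interaction intensity of a drug pair in the context of protein-protein
    interaction networks (Jaccard index of target sets, bounded simple-path
    counts, shortest and longest path lengths between target gene sets) and of
    signaling-pathway and cellular-process gene-set collections (common target
    pathways and processes). Includes readers and writers for drug-target,
    interaction-list, PPI edge-list and GMT gene-set files, a k-fold
    cross-validation protocol with uniform negative sampling, and a seeded
    synthetic-data generator that plants target sharing and PPI proximity into
    positive pairs so the whole pipeline is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
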