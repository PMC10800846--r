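Package: linesig
Title: Microbial Signatures Discriminating Host Lines with Transcriptome
    Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing small-intestinal microbiome differences
    between two divergently selected chicken lines and for discovering minimal
    microbial signatures that predict line membership. Implements low-count
    filtering, presence/absence partitioning, observed-OTU alpha diversity,
    weighted UniFrac beta diversity with principal coordinates analysis and
    PERMANOVA, per-OTU negative-binomial differential abundance with
    Benjamini-Hochberg and Bonferroni correction, a three-classifier
    (support-vector machine, single-hidden-layer perceptron, CART tree) by
    two-validation (stratified percent split, stratified k-fold hold-out)
    ensemble with information-gain plus p-value feature ranking and iterative
    dimensionality reduction, mean-relative abundance discretization into
    absent/low/medium/high classes, stage-two linkage of each signature
    microbe's abundance class to host gene-expression patterns with gene-list
    size optimization, and label-permutation negative controls. A coupled
    synthetic-data generator with planted signal makes every stage testable by
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    e1071,
    edgeR,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
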