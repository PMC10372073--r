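Package: immunocall
Title: Immune Cell Identification and Annotation from Single-Cell RNA-Seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies immune cells in gene-by-cell count matrices with a
    two-metric linear rule over a binarized leukocyte signature matrix
    (maximum Pearson correlation to the 22 LM22 profiles plus total
    signature-gene expression), assigns each immune cell to one of ten
    immune categories by maximum profile correlation, and refines T cells
    into CD4+ and CD8+ with a gradient-boosted classifier. Ships readers
    for 10x-style MatrixMarket triplets and dense tables, per-sample
    composition profiling with rank-based group comparison, evaluation
    utilities (confusion matrices, binomial confidence intervals, ROC),
    and a negative-binomial synthetic-data generator so the whole pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
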