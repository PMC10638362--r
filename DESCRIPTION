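Package: bfox
Title: Binary FOX Optimization Feature Selection with Half-Quadratic
    Ensemble Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for labeled numeric feature tables
    using binary variants of the FOX metaheuristic. Eight S- and V-shaped
    transfer functions binarize the continuous fox positions; candidate
    feature subsets are scored by a Gaussian Naive Bayes classifier under
    stratified cross-validation with minority oversampling, combined into a
    weighted multi-objective cost (accuracy, F-beta, AUC-ROC, selected
    feature fraction). Competing selector variants are benchmarked from
    multi-run (mean, SD) result tables via A-TOPSIS and Hellinger-TOPSIS,
    whose rank vectors are fused by robust half-quadratic aggregation with
    consensus and trust indices. Includes a synthetic generator for
    medical-image-derived feature tables and a locally linear embedding
    preprocessing stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    e1071,
    jsonlite,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
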