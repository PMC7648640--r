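Package: deconvbench
Title: Benchmarking Framework for Reference-Based Cell-Type Deconvolution
Version: 0.1.0
Authors@R:
    person("deconvbench", "maintainers", email = "maintainers@deconvbench.org",
           role = c("aut", "cre"))
Description: Tools to benchmark reference-based cell-type deconvolution of
    bulk transcriptomes. Generates pseudo-bulk mixtures with known
    composition from real or synthetic single-cell RNA-seq count data,
    builds per-type reference (signature) matrices, selects marker genes
    against the second-highest-expressing cell type, runs a grid of data
    transformations (linear, log, sqrt, VST), scaling/normalization
    strategies (column, min-max, z-score, quantile, upper-quartile, TPM,
    TMM, median-of-ratios, ...) and regression-based solvers (OLS, NNLS,
    robust, penalized, quadratic programming, nu-SVR, dampened weighted
    least squares), and scores every combination by RMSE and Pearson
    correlation, including missing-cell-type experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    DESeq2,
    glmnet,
    quadprog
Config/testthat/edition: 3
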