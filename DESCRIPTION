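Package: SimDeconv
Title: Simulation-Based Benchmarking of Cell-Type Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained toolkit for benchmarking single-cell-informed
    bulk RNA-seq deconvolution. Generates annotated synthetic single-cell
    references with controlled marker structure and mRNA-content differences,
    applies quality control and subsampling rules, simulates pseudo-bulk
    samples with scenario-driven composition and optional mRNA-content bias,
    builds and scores signature matrices (entropy specificity, Gini index,
    condition number), provides non-negative and dampened weighted least
    squares reference solvers, and runs benchmark experiments: accuracy
    metrics, mRNA-bias delta-RMSE, spillover, unknown content, annotation
    granularity, and leave-one-cell-type-out.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    pracma,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
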