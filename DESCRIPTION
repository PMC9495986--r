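Package: teaflow
Title: Reproducible Differential Expression Analysis for One-Color
    Microarray and Count Data
Version: 0.1.0
Authors@R:
    person("teaflow", "maintainers", email = "maintainers@teaflow.dev",
           role = c("aut", "cre"))
Description: A self-contained pipeline for differential expression
    analysis of one-color microarray intensities and RNA-seq counts:
    raw intensity preparation (normexp background correction, quantile
    normalization, median-polish summarization, replicate collapsing),
    conservative low-expression filtering, empirical-Bayes moderated
    t-tests, non-parametric rank-product tests with permutation-based
    proportion-of-false-positives estimates, precision weights for
    count data, quality-control statistics, annotation joining, and a
    deterministic options-file replay contract exposed through a small
    command line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
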