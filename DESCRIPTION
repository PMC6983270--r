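Package: decondoublet
Title: Deconvolution-Based Doublet Detection for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects heterotypic doublets in clustered single-cell RNA-seq
    data by deconvolving every cell against merged reference cluster
    signatures and comparing its deconvolution cell profile (DCP) to those of
    synthetic cell-pair mixtures, then rescues transitional or mixed-lineage
    singlet clusters that carry uniquely expressed genes. Includes reference
    cluster merging via a correlation threshold and Markov clustering,
    weighted synthetic doublet generation, a simplex-constrained non-negative
    least-squares solver, an aggregate-statistics one-way ANOVA with
    Tukey-Kramer post hoc tests for the rescue step, caller benchmarking
    utilities, and a ground-truth fixture simulator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
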