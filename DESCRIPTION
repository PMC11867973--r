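Package: plexscreen
Title: Multiplexed Hashed Single-Cell Drug Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for 96-plex cell-hashing drug perturbation
    screens read out by single-cell RNA-Seq. Provides combinatorial dual
    hashtag-oligo (HTO) demultiplexing of row/column antibody barcodes, cell
    quality control, graph-based clustering with marker detection,
    subsample-pseudobulk aggregation with negative binomial quasi-likelihood
    differential expression, hypergeometric over-representation analysis,
    signature activity scoring with bootstrap significance, dose-response
    fitting with drug sensitivity scores (DSS) and exact rank-sum group
    comparison, and occurrence counting over perturbation-signature (LINCS
    L1000 style) gene-set corpora. A fully labelled synthetic-data generator
    emulates the statistical structure of hashed plate screens so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    igraph,
    limma,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
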