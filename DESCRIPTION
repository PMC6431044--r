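Package: emptydrops
Title: Distinguishing Cells from Empty Droplets in Droplet-Based
    Single-Cell RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Calls cell-containing droplets in unfiltered droplet-based
    single-cell RNA-seq UMI count matrices by testing each barcode for
    deviation from the ambient RNA profile under a Dirichlet-multinomial
    model, with Monte Carlo p-values, a knee-point retention rule on the
    barcode-rank curve, and Benjamini-Hochberg correction with known
    positives. Includes the simple total-count baselines (knee point and
    expected-cell-count quantile rules), a synthetic fixture generator,
    and a labelled simulation and evaluation harness for measuring recall
    and the observed false discovery rate.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    edgeR,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    Rcpp,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
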