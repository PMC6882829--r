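Package: sctsne
Title: Faithful t-SNE Embeddings for Single-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A complete t-SNE protocol for bulk and single-cell
    transcriptomic data: sequencing-depth normalisation, dropout-based
    feature selection and PCA; perplexity-calibrated Gaussian affinities
    with nearest-neighbour truncation and multi-scale averaging; a
    Barnes-Hut t-SNE optimiser with PCA initialisation, data-size-dependent
    learning rate and exaggeration control; embedding quality metrics for
    micro- (KNN), meso- (KNC) and macroscopic (CPD) structure; out-of-sample
    positioning of new cells on a reference embedding with gene-bootstrap
    uncertainty hulls; and end-to-end recipes for standard and very large
    data sets, including a synthetic hierarchical Gaussian-mixture benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
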