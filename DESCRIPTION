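Package: scnf
Title: Single-Cell Clustering by Autoencoder Compression and Similarity
    Network Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised clustering of single-cell RNA-seq expression
    matrices. Genes are filtered with a non-negative-kernel autoencoder,
    cells are compressed into multiple stochastic latent representations
    by a variational autoencoder, per-latent cell-similarity networks are
    fused by iterative cross-diffusion of full and k-nearest-neighbor
    kernels, the number of cell types is estimated with the eigengap
    heuristic, and cells are partitioned by spectral clustering. Datasets
    above a configurable size are clustered on a random training sample
    and the labels are propagated to the remaining cells by k-nearest
    neighbor classification after weighted meta-clustering selects the
    most representative latent space. Includes evaluation metrics
    (adjusted Rand index, adjusted mutual information, V-measure,
    absolute log-modulus), a dropout-injection simulator, and a
    cluster-structured synthetic data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    igraph,
    stats,
    utils,
    graphics,
    methods
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    knitr
Config/testthat/edition: 3
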