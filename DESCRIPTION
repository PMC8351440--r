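Package: spaceclust
Title: Unsupervised Convolutional Clustering of Spatial Gene Expression Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns spatial-shape representations of per-gene expression
    images from spatial transcriptomics (Slide-seq, MERFISH and similar
    grid-resolved assays) by iterated pseudo-label training of a small
    convolutional network: features are embedded with UMAP, clustered with
    a Gaussian mixture model, sharpened into an auxiliary target
    distribution, and fed back as training targets under a bi-tempered
    logistic loss with optional center loss. The learned representations
    support calling spatially-expressed genes by ensemble neighbor
    stability, ranking spatial similarity between genes against a
    permutation null, and clustering genes into spatial patterns. Includes
    a simulator of patterned and unstructured gene images with mask and
    shared-permutation shuffle perturbations for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    uwot,
    mclust,
    data.table,
    Matrix,
    jsonlite,
    png,
    cluster,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
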