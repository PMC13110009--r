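Package: dcims
Title: Dimensional Cophenetic Integrity for Mass Spectrometry Imaging Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Unsupervised evaluation of dimensionality-reduction quality for
    mass spectrometry imaging (MSI) datacubes. Implements the Dimensional
    Cophenetic Integrity (DCI) score: representative pixels are sampled by
    k-means in the low-dimensional embedding, both spaces are hierarchically
    clustered (average linkage; cosine distance in the spectral space,
    Euclidean in the embedding), and the normalized mutual information
    between the two cophenetic distance structures measures how well the
    embedding preserves cluster relationships. Ships comparator metrics
    (co-k-nearest-neighbour accuracy, random-triplet accuracy, Spearman
    correlation of pairwise distances, centroid-distance correlation,
    mean-based Dunn index), a synthetic MALDI datacube generator, t-SNE and
    UMAP wrappers, grid search and Gaussian-process Bayesian optimization of
    embedding hyperparameters with DCI as the objective, continuous-mode
    imzML input/output, and embedding-to-RGB tissue rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    xml2,
    yaml,
    Rtsne,
    uwot,
    lhs,
    withr,
    rlang,
    tibble,
    ggplot2,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
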