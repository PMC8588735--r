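Package: circGCN
Title: Predicting circRNA-Disease Associations with a Graph Convolutional
    Network over Fused Similarity Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a complete pipeline for predicting circular RNA
    (circRNA)-disease associations from a heterogeneous network. Base
    similarities (Gaussian interaction profile kernels, gene-sharing
    similarity, chaos-game-representation sequence similarity, and
    DAG-based disease semantic similarity) are fused into comprehensive
    circRNA and disease similarity matrices, diffused with random walk
    with restart, reduced with principal component analysis, and fed to a
    one-layer graph convolutional encoder with a bilinear decoder trained
    by gradient descent to score unobserved circRNA-disease pairs.
    Includes k-fold cross-validation with negative sampling, a full
    classification metric suite, and a seeded synthetic-data generator
    with planted block structure so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
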