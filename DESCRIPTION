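Package: gdagae
Title: Gene-Disease Association Link Prediction with a Graph Convolutional Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ranks unobserved gene-disease pairs in a bipartite association
    network by embedding the graph with a two-layer graph-convolutional
    autoencoder (symmetric-normalized convolution, ReLU, dropout, inner-product
    decoder) and scoring candidate links by embedding dot products. Includes
    edge-list ingestion and degree statistics, train/validation/test edge
    splitting with negative sampling, evaluation from first principles
    (precision/recall, average precision, ROC, AUC, Youden best threshold),
    top-k candidate ranking, and a seeded bipartite block-model generator so
    the full pipeline runs and is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
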