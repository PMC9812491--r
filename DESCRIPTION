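Package: hetvgae
Title: Drug Repositioning with Heterogeneous Networks and Variational Graph
    Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-disease associations from a heterogeneous network
    that combines three Jaccard drug feature similarities (chemical
    substructures, target-protein domains, gene annotations), DAG-based
    disease semantic similarity, and known associations.  Node embeddings are
    learned with a two-layer graph-convolutional variational autoencoder and
    drug-disease pairs are classified with a convolutional head trained by
    mini-batch Adam.  Includes negative sampling, a five-fold protocol with
    an independent test fold, rank-based AUC/AUPR metrics, candidate
    ranking, and a fully seeded synthetic-data generator with planted
    cluster structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
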