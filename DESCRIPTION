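Package: hyperhda
Title: Dual-Channel Hypergraph Convolution for Herb-Disease Association
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts herb-disease associations from the multi-component,
    multi-target structure of herbal medicine. Herbs are modelled as
    hyperedges over their chemical components and diseases as hyperedges
    over their protein targets; node features come from Morgan-fingerprint
    Dice similarity (components) and global sequence-alignment similarity
    (targets), compressed by a single-layer autoencoder. A dual-channel
    hypergraph convolutional network with residual connections learns herb
    and disease embeddings whose sigmoid inner products score candidate
    associations. Includes balanced cross-validation with negative
    sampling, shuffle-robustness and cold-start protocols, ablation
    switches, and a seeded synthetic data generator with planted
    group structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ChemmineOB,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
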