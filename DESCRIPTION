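Package: semindex
Title: Hierarchical Semantic Indexing of Biomedical Abstracts with a
    Convolutional-Boltzmann Network
Version: 0.1.0
Authors@R:
    person("semindex", "maintainers", email = "semindex@example.org",
           role = c("aut", "cre"))
Description: Multi-label semantic indexing of biomedical title+abstract
    documents with controlled-vocabulary headings. Documents are encoded as
    fixed-length word-sequence embedding matrices enriched with Wikipedia-style
    category terms and lexicon-tagged entities; a small convolutional network
    extracts local sequence features, which are fused with a global
    entity-count feature inside a two-hidden-layer deep Boltzmann machine
    carrying label units; labels are predicted coarse-to-fine over k-means
    clusters of label embeddings. Includes macro/micro multi-label evaluation
    (precision, recall, F1, Jaccard-style similarity, ROC/AUC), a flat
    per-label binary baseline, and a seeded synthetic-corpus generator so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
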