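Package: egosig
Title: Active Signaling Signatures from Phosphoproteomics via Semantic
    Network Propagation and Ego Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts compact, functionally coherent active-signaling network
    signatures from phosphoproteomics log2 fold-change tables. Edges of a
    protein-protein interaction network are weighted by simGIC Gene Ontology
    semantic similarity and hub-corrected by square-root-degree (Laplacian)
    normalization. Differentially phosphorylated proteins seed a layered
    random walk with restart whose scores are filtered against a
    degree-preserving random-network ensemble; each surviving seed becomes the
    ego of a two-step ego network that is reduced by semantic z-score
    filtering and a joint topological/functional kernel-density selection into
    a supernode. Supernodes are linked by Jensen-Shannon distances between
    restart walks and partitioned into functional modules with the Leiden
    algorithm. Includes Fisher/Bonferroni enrichment and overlap-coefficient
    evaluation utilities and a synthetic-data generator with planted community
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
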