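Package: driversage
Title: Cancer Driver Gene Prioritization on Bipartite Gene-Sample Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes cancer driver genes from a cohort's somatic mutation
    and gene expression matrices together with a protein-protein interaction
    (PPI) network. Mutated genes are filtered by requiring a same-sample
    aberrantly expressed PPI neighbor, then gene and sample embeddings are
    learned on the bipartite gene-sample graph with a two-layer GraphSAGE
    encoder and a bidirectional cross-attention aggregator. A cosine-similarity
    decoder trained with weighted binary cross-entropy yields per-sample driver
    probabilities, and per-sample rankings are aggregated into a cohort-level
    driver list by Exponential Pairwise Voting, with a Condorcet (Copeland)
    baseline. Includes cross-validated evaluation, degree-preserving network
    negative controls, and a planted-driver cohort simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
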