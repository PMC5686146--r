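Package: mscnet
Title: Minimum Span Clustering of Sequence Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised, multi-level clustering of protein sequence
    similarity networks from all-vs-all BLAST E-values. Builds a
    symmetrized E-value distance matrix, grows clusters from each node's
    nearest neighbour in ascending-distance order, truncates intra-cluster
    bonds at a threshold estimated from the ratio of overall to
    intra-cluster edge-length distributions, and renormalizes clusters
    into coarser levels. Includes minimum-spanning-tree network export,
    minimum-distance family detection tuned by the F measure, Nei-Gojobori
    estimation of synonymous and nonsynonymous substitution rates with
    Jukes-Cantor correction, consistency scoring against a reference
    classification, and seed-deterministic synthetic data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    utils
Suggests:
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
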