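Package: linkcor
Title: Confounder Triplet Screening and Network Integration for Paired Omics
    Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Unsupervised integration of two paired numerical omics datasets
    measured on the same samples. Features of a "linker" dataset (e.g. gene
    expression) are screened as putative confounders of the pairwise
    correlations among features of a "vertex" dataset (e.g. metabolites): a
    triplet (vertex pair, linker) is flagged when conditioning on the linker
    significantly changes the vertex-pair correlation, assessed by comparing
    the zero-order and first-order partial correlation with a Steiger-type
    test for dependent correlations and Benjamini-Hochberg control across all
    triplets. Significant triplets are assembled into a weighted undirected
    graph, a bipartite graph, or a hypergraph incidence matrix, with network
    statistics, community detection, community-wise linker enrichment,
    cross-condition comparison, and a seeded latent-factor simulation
    benchmark reporting sensitivity, specificity and false discovery rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    parallel,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
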