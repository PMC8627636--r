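Package: mapsogs
Title: Graph-Based Gene Selection with a Many-Objective Binary Particle Swarm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid filter-wrapper gene selection for labelled expression data.
    Genes are pre-filtered by Fisher score, mapped to a weighted similarity
    graph (absolute Pearson correlation, sigmoid-normalised, thresholded),
    clustered with Louvain modularity optimisation, and a five-objective
    binary particle swarm searches for a small, diverse, discriminative gene
    subset (classification error, edge centrality, node centrality,
    specificity, subset size), with a repair operator that keeps every gene
    cluster represented. Includes a synthetic expression-data generator with
    planted correlated blocks, leave-one-out benchmarking for SVM, decision
    tree and k-nearest-neighbour classifiers, rank tables and the Friedman
    test for multi-method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    data.table,
    igraph,
    e1071,
    rpart,
    class
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
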