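Package: scGeneForest
Title: Label-Guided Random-Forest Feature Selection for Single-Cell
    Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Selects compact, non-redundant gene sets that discriminate
    cell types in single-cell RNA-seq expression matrices. Cell labels
    are first predicted by a spectral clustering flow (PCA, Euclidean
    k-nearest-neighbour graph, normalized-Laplacian spectral
    partitioning); skewed cluster sizes are then balanced by SMOTE
    oversampling of rare clusters combined with centroid-distance
    undersampling of major clusters; genes are scored by Gini-impurity
    importance from a forest of decision trees grown on all cells with
    random gene subspaces; the final gene set is obtained by a
    three-sigma importance cut followed by sequential removal of highly
    correlated genes under a dynamic Pearson-correlation threshold.
    Includes a seeded negative-binomial synthetic-data generator,
    clustering evaluation statistics (k-nearest-neighbour consistency,
    balance entropy), readers and writers for delimited, Matrix Market
    and 10x-style inputs, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    data.table,
    igraph,
    jsonlite,
    mclust,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
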