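Package: breathclust
Title: Unsupervised Cross-Clustering of Breathomics Peak Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cluster analysis toolkit for pre-processed metabolomics peak
    matrices (samples by metabolites), with a focus on exhaled-air (VOC)
    profiling. Computes pairwise similarity and dissimilarity matrices
    (Pearson, Spearman, Euclidean) over either axis, clusters them by
    hierarchical agglomeration or by transitivity clustering (weighted
    cluster editing with an exact branch-and-bound solver and a seeded
    pivot heuristic), scores clusterings internally (silhouette) and
    externally (F-measure against annotation labels) across threshold
    sweeps, embeds dissimilarities in two or three dimensions by
    stress-majorization multidimensional scaling, and runs a layered
    cross-clustering workflow that splits the metabolite set into
    correlated subsets and ranks each subset by how well it explains
    sample annotations, exposing confounder-associated metabolite groups
    (smoking, nutrition) that mask the disease signal. Includes a
    synthetic-data generator with planted metabolite groups for testing
    and demonstration, plus delimited-text readers and writers for every
    intermediate result and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
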