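Package: scMCGF
Title: Multi-View Graph Fusion Clustering for Single-Cell RNA-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Clusters single cells by jointly learning per-view similarity
    graphs and a weighted unified graph from four representations of a
    scRNA-seq expression matrix (pre-processed expression, pathway activity
    scores, PCA features and diffusion-map features), and enforcing a rank
    constraint on the unified graph Laplacian so that its connected
    components are the clusters. Includes the standard scRNA-seq
    pre-processing steps (conditional log transform, sparse-gene filtering,
    size-factor normalization, highly variable gene selection), AUCell-style
    gene-set activity scoring, clustering metrics (clustering accuracy,
    NMI, ARI), a synthetic data generator for testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    quadprog,
    mclust,
    cluster,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
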