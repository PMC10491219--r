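Package: cytotraj
Title: Trajectory Analysis of Mass Cytometry Data with Anchor-Based Batch Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for single-cell mass cytometry (CyTOF)
    analysis of hematopoietic stem and progenitor cells: arcsinh
    transformation and percentile scaling, anchor-sample batch correction
    (median alignment, half-normal resampling of introduced negatives, and
    99.8th-percentile downward normalization), hierarchical gating, balanced
    downsampling, knn-graph construction, diffusion-map embedding, Leiden
    over-clustering, partition-graph cluster connectivity, root-anchored
    pseudotime, cluster-constrained knn label transfer across tissues, and
    downstream statistics (binned pseudotime trajectories with derivative and
    inflection analysis, Manhattan-distance sample dissimilarity, Wilcoxon
    group comparisons with FDR control). Includes a synthetic-data generator
    that emulates multi-batch, multi-tissue CyTOF data over a branching
    hematopoietic lineage with known ground truth, plus minimal FCS 3.1
    read/write support.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    BiocNeighbors,
    RSpectra,
    matrixStats,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
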