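Package: transcriptogram
Title: Transcriptogram Analysis of Case-Control Expression on a PPI-Ordered Gene List
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systems-level differential expression along a protein-protein
    interaction (PPI) derived one-dimensional gene ordering. Genes are seriated
    so that interacting genes occupy nearby positions (simulated annealing on
    the weighted linear arrangement cost), expression is projected through a
    sliding window over the ordering, each window position is tested
    case-versus-control with empirical-Bayes moderated t-statistics, and
    maximal runs of significant positions are called as differentially
    expressed clusters. Cluster PPI subnetworks, inner/outer connectivity,
    interactome coverage and cross-analysis cluster matching are computed,
    together with hypergeometric GO over-representation per cluster and
    Jaccard-similarity term dendrograms. Sample grouping by PCA plus Ward
    hierarchical clustering and pairwise marker-gene tests support time-course
    designs. A synthetic planted-module generator provides ground truth for
    end-to-end recovery tests.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    limma,
    ape,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
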