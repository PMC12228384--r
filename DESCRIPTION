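Package: roikey
Title: Key-Gene Discovery from ROI-Level Spatial Transcriptomics Counts
Version: 0.1.0
Authors@R:
    person("roikey", "maintainers", email = "roikey@example.org", role = c("aut", "cre"))
Description: A tested pipeline for region-of-interest (ROI) level spatial
    transcriptomics count data: between-sample signal-intensity normalization,
    replicate-based removal of unwanted variation, negative-binomial Wald
    differential expression with Benjamini-Hochberg adjustment, gene-set
    over-representation analysis (hypergeometric p, odds ratio, combined
    score), and key-gene prioritization by fold-change-seeded random walk
    with restart plus betweenness centrality on a protein-protein interaction
    network. Includes a synthetic-data module that emulates the ROI design,
    negative-binomial count structure, slide-level batch factors, and planted
    group effects that the downstream stages assume, so the whole pipeline is
    testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
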