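Package: qqppi
Title: Query-Query Protein-Protein Interaction Networks for Disease Marker
    Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and analyses Query-Query protein-protein interaction
    (QQPPI) networks from case/control expression data. Differentially
    expressed genes are selected by two-sample t statistics and by
    Significance Analysis of Microarrays (SAM) with permutation-based false
    discovery rate estimation, filtered through a hypergeometric gene-set
    over-representation test, and used as queries to induce subnetworks of
    one or more interactomes. Network nodes are classified as hubs (degree
    at least mean plus twice the standard deviation of the degree
    distribution) or bottlenecks (high betweenness, sub-cutoff degree, at
    least two hub neighbours); 3- and 4-cliques are enumerated into core
    functional modules; cliques are matched against a protein-complex
    catalog; per-edge Pearson co-expression is compared between control and
    disease groups; and previously unreported disease markers are
    identified and annotated. A seeded synthetic-data module generates
    expression matrices, interactomes, complex catalogs and term
    annotations with planted ground truth for calibration and recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, DifferentialExpression,
    GeneExpression, Network
RoxygenNote: 7.3.3
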