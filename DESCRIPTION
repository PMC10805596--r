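Package: scProteoNet
Title: Coexpression Networks of Neuronal Protein Homeostasis from Single-Cell Cluster Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds robust gene coexpression networks from clustered
    single-cell expression data by correlating per-gene vectors of pairwise
    cluster fold changes, a transform that sidesteps the missing-value
    structure of single-cell counts. Supports selective networks restricted
    to genes overexpressed in a target cell class, size-3 motif filtering,
    greedy-modularity module detection, and connectivity statistics against
    uniform random-graph nulls. Cross-species conservation of coexpression
    interactions is scored against degree-preserving network randomizations
    through a one-to-one orthologue map. Includes a negative-binomial
    single-cell simulator with planted coregulated modules and planted
    conserved edges for end-to-end validation, cell-class differential
    expression and variability statistics, gene-family cumulative expression
    summaries, and a reproducible pipeline driver with a machine-readable
    run manifest.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    ape,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
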