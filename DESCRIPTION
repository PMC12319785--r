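Package: retestconn
Title: Test-Retest Reliability of Task-Modulated Functional Connections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies task-contrast functional connections that are
    consistent across two measurement sessions and characterizes the
    behavioral, functional, and structural properties that distinguish
    consistent from inconsistent connections. Implements mass-univariate
    paired t-test selection of source-space coherence contrasts with a
    spatial distance filter, single-linkage bundle clustering of
    supra-threshold connections, parcel-level aggregation, ICC(3,1)
    consistency analysis with F-based confidence intervals, per-edge
    behavioral regression screens, chi-square and Mann-Whitney group
    comparisons, and weighted structural-connectome metrics (shortest
    path length, edge betweenness centrality). A synthetic-data module
    generates multi-subject connectivity, behavior, and structural
    connectomes with planted ground truth so every stage has a
    parameter-recovery test.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
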