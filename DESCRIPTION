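Package: coexnet
Title: Cross-Cohort Validated Weighted Co-Expression Network Analysis
Version: 0.1.0
Authors@R:
    person("coexnet", "developers", email = "coexnet@example.org",
           role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks from bulk
    transcriptome cohorts (soft-threshold adjacency, topological overlap,
    hierarchical community detection, eigengene merging), validates edges
    and communities in independent cohorts (per-edge replication and
    permutation preservation Z statistics), relates community eigengenes
    to clinical traits (Pearson correlation, Welch t, one-way ANOVA),
    tests communities for gene-set over-representation against a
    rest-of-network background, fits tercile-coded Cox proportional
    hazards models for prognosis, and constructs propensity-matched
    control groups. A multi-cohort synthetic data generator with planted
    community structure, trait links and proportional-hazards survival
    makes the whole pipeline testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    survival,
    withr
Config/testthat/edition: 3
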