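Package: agemirnet
Title: Age-Correlation Screening and miRNA-mRNA Anti-Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens feature-by-sample expression matrices (miRNA and gene)
    for monotone association with continuous age at diagnosis using Spearman
    rank correlation with exact permutation p-values on tie-free covariates,
    selects tumor-specific age-correlated candidate miRNAs by contrasting
    tumor against non-neoplastic tissue, and builds a bipartite
    miRNA-to-target anti-correlation integration network exportable to
    Cytoscape (SIF, GraphML). Includes a synthetic-cohort simulator with
    planted age signals and planted miRNA-target repression for ground-truth
    validation, 2^-ddCt relative-quantification helpers, and clinical-cohort
    composition tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
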