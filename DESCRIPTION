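Package: netpharm
Title: Network Pharmacology of Disease Genes and Drug Targets
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An offline network-pharmacology toolkit for integrating
    disease-gene evidence with predicted drug targets. Fuses per-source gene
    lists under a k-of-n retention rule, builds drug-target consensus sets,
    constructs undirected protein-protein interaction networks and computes
    the full Cytoscape-style topology panel (degree, betweenness, closeness,
    diameter, characteristic path length, clustering coefficient, density,
    heterogeneity, centralization), detects dense molecular complexes with
    the MCODE algorithm, quantifies network fragility under targeted hub
    removal, performs exact hypergeometric over-representation tests with
    fold enrichment and Benjamini-Hochberg FDR plus kappa-based clustering
    of enriched terms, and overlays transcription-factor regulons on hub
    sets. Includes seeded synthetic-data generators so every stage is
    testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
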