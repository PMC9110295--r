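Package: proteokg
Title: Clinical Proteomics Knowledge Graphs and Automated Analysis Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An embedded property-graph store for clinical proteomics
    knowledge (typed nodes and relationships with attributes, schema
    validation, TSV/JSON/GML/GraphML import and export), together with the
    automated analysis pipeline that turns a quantified proteomics matrix
    into a statistics report and a prior-knowledge summary subgraph:
    missing-value filtering, KNN/MinProb/mixed imputation, normalization,
    design-aware differential testing with Benjamini-Hochberg or
    permutation-based false discovery rates, SAM statistics, correlation
    networks with Louvain clustering, betweenness-centrality knowledge
    summarization, Kaplan-Meier survival stratification, and a drug
    prioritization workflow based on side-effect dissimilarity and
    literature co-mentions. Seeded generators provide miniature
    schema-conformant knowledge graphs and simulated experiments so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    survival,
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
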