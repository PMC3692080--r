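Package: gsora
Title: Gene-Set Over-Representation Analysis for Plant Gene Lists
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Over-representation analysis of query gene lists against
    categorized gene-set collections (GO-derived, gene-family, curated and
    motif-based sets). Provides exact hypergeometric and Fisher tests and a
    Yates-corrected chi-squared approximation on the 2x2 overlap table, six
    multiple-testing corrections (Bonferroni, Holm, Hochberg, Hommel,
    Benjamini-Hochberg, Benjamini-Yekutieli), custom analysis backgrounds,
    GMT gene-set input/output with provenance sidecars, Gene Ontology DAG
    propagation under the true-path rule with Graphviz DOT hierarchy export,
    conversion among gene locus, gene symbol and microarray probe-set
    identifiers, annotation-coverage reporting, and a seeded synthetic-data
    generator so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
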