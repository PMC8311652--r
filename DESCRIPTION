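Package: epidrugminer
Title: Knowledge Discovery for Drug Interactions with Epigenetic Enzymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computational knowledge-discovery workflow for
    pharmacoepigenetics. Provides a validated registry of human enzymes
    catalysing classical epigenetic reactions (DNA methylation and histone
    modifications), a boolean literature-query engine with PubMed-style
    wildcard and field-tag semantics, bibliometric citation statistics
    including a saturating citation-expectation model, construction of a
    binary drug-by-enzyme interaction matrix from DrugBank-style records,
    and over/under-representation analysis of gene sets over an ontology
    DAG with Bonferroni correction, detail-term detection and headline
    selection. Seeded synthetic-data generators emulate every input so the
    full pipeline is reproducible offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
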