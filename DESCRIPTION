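Package: phenotriage
Title: Ontology-Driven Literature Search and Document Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An ontology-driven search-and-triage engine for biomedical
    literature. Parses OBO-format phenotype ontologies and serves ranked
    as-you-type term suggestions matched against every text field of every
    term; reads MEDLINE-style citations and builds a field-aware inverted
    index with tf-idf weighting and vector-space cosine ranking;
    enumerates sensitivity-encoded word combinations of selected phenotype
    names with per-combination match counts; and models a three-stage
    interactive triage session with query-result heatmaps, term
    distribution matrices, term-encoded abstracts, dwell-based visited
    marks and a selected-document pile. A deterministic synthetic-fixture
    generator produces ontologies and citation corpora with controlled
    term-frequency structure for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
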