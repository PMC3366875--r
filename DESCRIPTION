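Package: ehrlit
Title: EHR-Driven MeSH Keyword Identification and Literature Query Building
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies Medical Subject Headings (MeSH) concepts in the
    narrative sections of HL7 Clinical Document Architecture (CDA) electronic
    health records, filters them by configurable section relevance, MeSH tree
    branches and negation, and iteratively builds PubMed-style Boolean queries
    that retrieve citations sharing a maximal number of MeSH terms with the
    record. Includes a deterministic local citation backend implementing the
    query semantics, an optional NCBI E-utilities client, precision/recall
    evaluation against gold annotations, citation-reduction trajectories, and
    seeded generators for mini-MeSH thesauri, CDA documents and MeSH-indexed
    citation corpora so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    jsonlite,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
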