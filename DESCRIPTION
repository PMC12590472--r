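Package: phemap
Title: Cross-Species Phenotype Ontology Mapping Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for aligning a mammalian phenotype ontology with a human
    phenotype ontology: an OBO-dialect reader/writer with scoped synonyms and
    entity-quality (EQ) logical definitions, a token-bag lexical matcher that
    classifies hits with SKOS mapping predicates from the synonym-scope matrix,
    logical-definition matching and reconciliation reports, SSSOM TSV mapping
    input/output (including a free-text sign/symptom dialect), priority-based
    merging of manual, logical and lexical mapping sets, pattern-driven
    generation of logical definitions, and ontology quality-control and
    deprecation operations.  A seeded fixture generator produces paired
    mini-ontologies with planted ground-truth mappings for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
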