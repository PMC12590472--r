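# phemap — cross-species phenotype ontology mapping toolkit

Mouse phenotype data are annotated with a mammal-wide phenotype ontology
(MP-style ids); human clinical data with a human-specific one (HP-style
ids). Moving evidence across the species barrier requires explicit
term-to-term mappings, and producing them reliably takes several
cooperating tools. phemap implements that toolchain for R:

* **Ontology model + OBO dialect** — terms with scoped synonyms
  (EXACT/NARROW/BROAD/RELATED), text definitions, `is_a` parents,
  entity–quality (EQ) logical definitions, and deprecation metadata;
  `parse_obo()` / `write_obo()` are exact inverses on the dialect.
* **Lexical matcher** — `lexical_match()` compares token bags (all words
  must match; order, case and punctuation ignored) of every label and
  synonym pair and classifies each hit with a SKOS predicate from the
  synonym-scope matrix: label/exact × label/exact → `skos:exactMatch`,
  an MP narrow synonym against an HP label/exact synonym →
  `skos:narrowMatch`, the mirrored cells → `skos:broadMatch`, everything
  weaker → `skos:relatedMatch`. Mappings are always MP-subject,
  HP-object.
* **Logical matcher** — `logical_match()` pairs terms whose EQ
  definitions (quality genus + `(relation, filler)` modifier set, e.g.
  `PATO:0000051` + `characteristic_of_part_of UBERON:0002387` +
  `has_modifier PATO:0000460`) are identical under canonical comparison.
* **SSSOM I/O** — deterministic TSV reader/writer with metadata header,
  strict predicate validation and extra-column preservation, plus the
  free-text sign/symptom dialect (description → pipe-delimited MP and HP
  ids → sources).
* **Merging + reports** — `merge_mappings()` collapses manual, logical
  and lexical sets to one row per term pair (manual > logical > lexical,
  then exact > narrow > broad > close > related);
  `report_exact_without_logical_agreement()`,
  `report_logical_without_exact_mapping()` and
  `report_multi_exact_lexical()` produce the curator review lists.
* **Pattern engine** — `apply_pattern()` stamps template-generated EQ
  definitions onto terms from a filler spreadsheet, replacing whatever
  was there.
* **Editing + QC** — `obsolete_term()` deprecates without ever deleting
  an id; `qc_check()` reports missing definitions, label-equal
  synonyms, duplicate synonyms, shared exact synonyms and invalid EQ
  relations.
* **Fixtures** — `generate_fixture_pair()` builds seeded paired
  mini-ontologies with planted ground-truth mappings, one per matrix
  cell, plus near-miss decoys.

A command-line wrapper (`exec/phemap`, or `phemap_cli()` in-process)
exposes `lexmatch`, `logmatch`, `merge`, `diff-logdefs`,
`report-multiexact`, `qc`, `apply-patterns`, `fixtures` and `convert`.

## Worked example

The term "decreased bone mineral density" carries the exact synonyms
"osteopenia" and "reduced bone mineral density"; the human side has the
terms "Osteopenia" and "Reduced bone mineral density":

```r
library(phemap)
mp <- ontology("MP", list(
  pheno_term("MP:0000063", "decreased bone mineral density",
             definition = "Reduction in bone mineral per unit area.",
             synonyms = list(synonym("osteopenia", "exact"),
                             synonym("reduced bone mineral density", "exact")))))
hp <- ontology("HP", list(
  pheno_term("HP:0000938", "Osteopenia",
             definition = "Mild reduction of bone mineral density."),
  pheno_term("HP:0004349", "Reduced bone mineral density",
             definition = "Reduction of bone mineral density.")))
lexical_match(mp, hp)$mappings[, c("subject_id", "predicate_id", "object_id")]
#>   subject_id    predicate_id object_id
#> 1 MP:0000063 skos:exactMatch HP:0000938
#> 2 MP:0000063 skos:exactMatch HP:0004349
```

One mouse term matches two human terms exactly — the situation
`report_multi_exact_lexical()` flags for review. Demoting the
"osteopenia" synonym to `narrow` scope and re-matching turns the first
row into `skos:narrowMatch`: the human term now counts as the narrower
concept, and the change propagates automatically whenever matches are
regenerated.

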