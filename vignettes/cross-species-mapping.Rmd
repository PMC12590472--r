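---
title: "Aligning mouse and human phenotype ontologies with phemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning mouse and human phenotype ontologies with phemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phemap)
```

## The problem

Mouse phenotype annotations are recorded against a mammal-wide phenotype
vocabulary (MP-style ids), clinical annotations against a human-specific
one (HP-style ids).  The two ontologies describe overlapping biology with
different labels, different granularity and different structure, so
translating between them needs explicit term-to-term mappings.  phemap
implements the machinery that produces, reconciles and merges such
mappings: lexical matching over labels and scoped synonyms, logical
matching over entity--quality (EQ) definitions, SSSOM mapping-set I/O,
priority-based merging, curator discrepancy reports, pattern-driven
logical-definition generation, and the ontology editing/QC operations
that the mapping work feeds back into.

Throughout the package the mouse-side term is the mapping **subject** and
the human-side term the **object**.  Under that convention
`skos:narrowMatch` asserts that the human term covers a narrower concept
than the mouse term, and `skos:broadMatch` a broader one.

## Lexical matching

Two strings match when their **token bags** are equal: both are
lowercased, punctuation (`,;:.()/'-`) becomes whitespace, and the
resulting word multisets are compared.  All words have to match; word
order, case and punctuation do not matter, and multiplicity is kept (so
"cleft lip, cleft palate" is not the bag of "cleft lip palate").  There
is deliberately no stemming and no spelling normalization: "hypospadia"
and "Hypospadias" do **not** match, which is the desired behaviour --
that pair differs in meaning (the human term is male-specific) and is
related only through a curated narrowMatch.  British spelling variants
are expected to be present as synonyms rather than handled by the
matcher.

Each hit is classified by where the matching strings came from.  With
fields `label`, `exact`, `narrow`, `broad`, `related` on each side (a
term label behaves exactly like an exact synonym), the predicate matrix
is:

| subject \\ object | label/exact | narrow | broad | related |
|---|---|---|---|---|
| **label/exact** | exactMatch | broadMatch | narrowMatch | relatedMatch |
| **narrow** | narrowMatch | relatedMatch | relatedMatch | relatedMatch |
| **broad** | broadMatch | relatedMatch | relatedMatch | relatedMatch |
| **related** | relatedMatch | relatedMatch | relatedMatch | relatedMatch |

The directional cells follow from the SKOS reading above: a subject-side
*narrow* synonym names a narrower concept than its term, so when it
matches an object label the object term is the narrower one --
narrowMatch -- and symmetrically for *broad*.  Cells where both scopes
are inexact carry too little information for a direction and degrade to
relatedMatch, as does anything involving a *related* synonym.
`skos:closeMatch` is reserved for manual curation and never emitted
lexically.  When one pair of terms matches through several field pairs,
the single kept mapping takes the highest-priority predicate
(exact > narrow > broad > related).  Swapping the two ontologies
exchanges narrowMatch and broadMatch and fixes exact/related, a property
the test suite checks on randomly generated fixtures.

```{r}
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
```

Both hits are exact matches through synonyms.  A curator reviewing terms
with more than one exact match (`report_multi_exact_lexical()`) might
decide "osteopenia" really names a narrower concept; demoting the
synonym scope to `narrow` turns the first mapping into a
`skos:narrowMatch` the next time matches are generated.

## Logical definitions and logical matching

An EQ definition couples a quality genus (a PATO term such as
"morphology") to modifier pairs like
`characteristic_of_part_of UBERON:0002387` ("pes") and
`has_modifier PATO:0000460` ("abnormal").  `eq_equal()` compares
canonical forms -- modifiers are a set, sorted by (relation, filler) --
and treats relations as opaque identifiers: `characteristic_of` versus
`characteristic_of_part_of`, or two different anatomical fillers, make
definitions unequal.  No reasoning over relation or class hierarchies is
attempted, and `logical_match()` therefore emits `skos:exactMatch` only:
without subsumption reasoning there is no sound basis for directional
logical matches.

Identity of logical definitions is a statement about the definitions,
not necessarily about meaning: a pair can share a logical definition yet
be curated as a narrowMatch because the textual definition carries
nuance (bilaterality, for instance) the logical one misses.
`report_logical_without_exact_mapping()` surfaces exactly those pairs;
`report_exact_without_logical_agreement()` surfaces the converse, exact
manual mappings whose logical definitions are absent or differ, the
working list for definition reconciliation.

## Patterns

`read_pattern()` loads a small YAML template whose genus and modifier
fillers are constants or declared variables; each variable constrains the
ontology prefix of its fillers (an anatomical-entity variable takes
UBERON ids only).  `apply_pattern()` validates the filler table, then
**replaces** each listed term's logical definition with the instantiated
template -- regeneration from patterns is the source of truth for those
terms, so any hand-written definition is discarded, and re-application
is a no-op.  Label/definition/synonym generation from patterns is out of
scope here.  The YAML serialization is this package's own minimal
format: it mirrors the constant/variable structure of phenotype design
patterns without pulling in a full templating system.

## SSSOM I/O and merging

Mapping sets are written as SSSOM TSV: `#key: value` metadata lines,
then columns `subject_id, subject_label, predicate_id, object_id,
object_label, mapping_justification, author_id, mapping_date, comment`,
rows sorted by subject then object so the writer is byte-deterministic.
The in-memory `method` enum (manual/logical/lexical) is the source of
truth and is serialized as a semapv-style justification token.  Several
curator ORCIDs share one pipe-delimited cell.  Predicate values are
strict (`skos:exactmatch` is a row error, not a silent fix), unknown
extra columns ride along unchanged, and the reader/writer pair is an
identity on the dialect.  A second dialect handles free-text
sign/symptom tables: a description column, pipe-delimited MP and HP id
columns (either may be empty -- "brain fog" has no mouse-side term) and
source citations.

`merge_mappings()` collapses any number of sets to one row per (subject,
object) pair: methods rank manual > logical > lexical, predicates rank
exact > narrow > broad > close > related within the winning method, and
losing rows are recorded in the winner's comment.  `closeMatch` sits
between broad and related as the package's own choice -- directional
matches carry more information than close, close more than related --
and the ordering is configurable through `merge_policy()`.  Collapsing
is per pair of terms, not per subject.  The merge is idempotent,
input-order invariant and never invents rows.

## Ontology model, editing and QC

The OBO-dialect reader/writer covers the tags the mapping work needs
(id, name, def, scoped synonyms, is_a, intersection_of, is_obsolete,
replaced_by, contributor/created_by, creation_date); anything else
round-trips opaquely, and `parse_obo(write_obo(x))` is an identity on
the dialect.  Ids are never deleted: `obsolete_term()` flips the
deprecation flag, clears the logical definition and the `is_a` parents
(an obsolete term with parents is not valid OBO), optionally points
`replaced_by` at a successor and transfers the victim's label to it as
an exact synonym.  Deprecated terms are excluded from matching and QC
and are written with the conventional "obsolete " label prefix.

`qc_check()` reports missing definitions, synonyms equal to their term's
label, duplicated synonyms within a term, exact synonyms shared between
terms, and (given an allow-list) unknown EQ relations.  Comparisons use
the same normalizer as the matcher; that is a documented choice -- a
case-insensitive check may flag slightly more than a byte-exact one, and
erring toward more findings is the right direction for a curation
report.  Dangling `is_a` targets are reported by `dangling_parents()`
rather than treated as errors, because fragments of large ontologies are
normal inputs.

## The fixture generator

`generate_fixture_pair(seed, n_planted_per_cell, n_decoys)` builds an
MP-like and an HP-like mini-ontology plus the ground-truth mapping set.
For every cell of the match matrix it plants term pairs whose match
arises from exactly that cell: the match text is placed in the stated
field on each side, with word order permuted and the human-side string
capitalized so that only the token-bag rule can recover it; every other
label is a globally unique token bag drawn from a built-in vocabulary of
anatomy and quality words.  Decoys share at least one token with a
planted label but never a whole bag, probing the boundary of the
"all the words must match" rule.  Every term gets a definition so a
fresh fixture is QC-clean, and output is byte-deterministic per seed.

What the generator does *not* emulate: real synonym noise (abbreviations,
acronyms, British spellings), deep is_a hierarchies, and release-scale
term counts.  Passing tests on fixtures therefore demonstrate the
correctness of the matching, merging and reporting *rules*, not recall
on any actual ontology release; release-level counts depend on external
curated files and are out of scope.

## Numerical and design choices

* Normalization is fixed (lowercase, the punctuation class above); it is
  documented rather than guessed from any particular production system.
* Determinism everywhere: writers sort rows, the generator and all
  randomized tests run under explicit seeds, and the CLI records tool
  version and parameters in output headers so identical invocations give
  byte-identical artifacts.
* Test and check problem sizes (fixtures of a few dozen terms, 100-seed
  property sweeps) were chosen so the whole suite runs in well under a
  minute while still exercising every matrix cell and merge combination.
* Degenerate inputs: empty ontologies, empty mapping sets and empty
  token bags are all legal and yield empty outputs; an all-punctuation
  label simply never matches.

## Limitations

No OWL reasoning or subsumption-based matching; no fuzzy or embedding
similarity; single ontology pair per run; SSSOM support is the TSV
dialect described here, not full schema validation of the published
model.  These boundaries are deliberate: the package implements the
deterministic, reviewable core of the alignment workflow, and everything
it cannot decide mechanically it hands to a curator as a report.
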