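test_that("OBO stanzas parse into terms with scoped synonyms and EQ defs", {
  doc <- c(
    "format-version: 1.2",
    "ontology: mp",
    "",
    "[Term]",
    "id: MP:0003124",
    "name: hypospadia",
    'def: "Urethral opening on the ventral surface." []',
    "",
    "[Term]",
    "id: MP:0000063",
    "name: decreased bone mineral density",
    'synonym: "osteopenia" NARROW []',
    'synonym: "reduced bone mineral density" EXACT []',
    "is_a: MP:0000001 ! parent label",
    "intersection_of: PATO:0001790",
    "intersection_of: characteristic_of_part_of UBERON:0001474",
    "intersection_of: has_modifier PATO:0000460",
    "xref: external:id",
    "contributor: https://orcid.org/0000-0003-4606-0597",
    "creation_date: 2024-05-01T12:00:00Z")
  onto <- parse_obo(doc)
  expect_s3_class(onto, "pheno_ontology")
  expect_identical(onto$prefix, "MP")
  expect_identical(length(onto$terms), 2L)
  expect_identical(onto$terms[["MP:0003124"]]$label, "hypospadia")
  t <- onto$terms[["MP:0000063"]]
  expect_identical(t$synonyms[[1L]], synonym("osteopenia", "narrow"))
  expect_identical(t$parents, "MP:0000001")
  expect_identical(t$logical_def$genus, "PATO:0001790")
  expect_identical(nrow(t$logical_def$modifiers), 2L)
  expect_identical(t$other, "xref: external:id")
  expect_identical(t$contributors, "https://orcid.org/0000-0003-4606-0597")
})

test_that("malformed and duplicate stanzas are rejected; empty doc is empty", {
  expect_error(parse_obo(c("[Term]", "name: no id here")), "stanza 1")
  expect_error(
    parse_obo(c("[Term]", "id: MP:0000001", "name: a",
                "", "[Term]", "id: MP:0000001", "name: b")),
    "duplicate term id")
  onto <- parse_obo("format-version: 1.2\nontology: mp\n")
  expect_identical(length(onto$terms), 0L)
})

test_that("parse/write round-trips are identity, including obsolete labels", {
  o0 <- ontology("MP", list())
  expect_identical(parse_obo(write_obo(o0)), o0)

  one <- ontology("HP", list(
    pheno_term("HP:0000001", "All", definition = 'Root "class" \\ thing.',
               synonyms = list(synonym("everything", "related")))))
  expect_identical(parse_obo(write_obo(one)), one)

  for (seed in c(11L, 12L, 13L)) {
    fx <- generate_fixture_pair(seed, 2L, 5L)
    expect_identical(parse_obo(write_obo(fx$mp)), fx$mp)
    expect_identical(parse_obo(write_obo(fx$hp)), fx$hp)
  }

  mid <- obsolete_term(midface_fixture(), "MP:0009855", "MP:0012085")
  rt <- parse_obo(write_obo(mid))
  expect_identical(rt, mid)
  expect_match(write_obo(mid), "name: obsolete midface retrusion", fixed = TRUE)
})

test_that("obsoletion deprecates in place without deleting the id", {
  onto <- midface_fixture()
  out <- obsolete_term(onto, "MP:0009855", merge_into = "MP:0012085")
  victim <- out$terms[["MP:0009855"]]
  expect_true(victim$deprecated)
  expect_identical(victim$replaced_by, "MP:0012085")
  expect_null(victim$logical_def)
  expect_true("MP:0009855" %in% names(out$terms))
  target <- out$terms[["MP:0012085"]]
  expect_true(any(vapply(target$synonyms, function(s)
    s$text == "midface retrusion" && s$scope == "exact", TRUE)))
  expect_identical(setdiff(names(onto$terms), names(out$terms)), character(0))

  no_merge <- obsolete_term(onto, "MP:0009855")
  expect_true(no_merge$terms[["MP:0009855"]]$deprecated)
  expect_null(no_merge$terms[["MP:0009855"]]$replaced_by)
  expect_identical(length(no_merge$terms[["MP:0012085"]]$synonyms), 0L)

  expect_error(obsolete_term(onto, "MP:9999999"), "unknown term")
  expect_error(obsolete_term(onto, "MP:0009855", "MP:0009855"), "itself")
  expect_error(obsolete_term(out, "MP:0009855"), "already deprecated")
})

test_that("QC findings match an independent brute-force re-scan", {
  ppi <- ontology("MP", list(
    pheno_term("MP:0009142", "decreased prepulse inhibition",
               definition = "Reduced prepulse inhibition.",
               synonyms = list(synonym("decreased PPI", "exact"))),
    pheno_term("MP:0014256", "decreased paired-pulse inhibition",
               definition = "Reduced paired-pulse inhibition.",
               synonyms = list(synonym("decreased PPI", "exact"))),
    pheno_term("MP:0000010", "no definition yet"),
    pheno_term("MP:0000011", "self titled",
               definition = "Has a synonym equal to its own label.",
               synonyms = list(synonym("Self-titled", "exact"),
                               synonym("twin", "related"),
                               synonym("twin", "broad")))))
  rep <- qc_check(ppi)
  expect_identical(rep$missing_definitions, "MP:0000010")
  expect_identical(nrow(rep$shared_exact_synonyms), 1L)
  expect_identical(rep$shared_exact_synonyms$term_ids,
                   "MP:0009142|MP:0014256")
  expect_identical(rep$synonym_equals_label$term_id, "MP:0000011")
  expect_identical(rep$duplicate_synonyms_within_term$synonym, "twin")

  # brute-force re-scan of shared exact synonyms
  keys <- list()
  for (t in ppi$terms) {
    if (t$deprecated) next
    for (s in t$synonyms) {
      if (s$scope != "exact") next
      k <- paste(normalize_label(s$text), collapse = " ")
      keys[[k]] <- union(keys[[k]], t$id)
    }
  }
  brute <- sum(vapply(keys, function(x) length(x) >= 2L, TRUE))
  expect_identical(nrow(rep$shared_exact_synonyms), brute)

  # deprecated terms are exempt everywhere
  dep <- obsolete_term(ppi, "MP:0000010")
  expect_identical(qc_check(dep)$missing_definitions, character(0))

  clean <- generate_fixture_pair(5L, 2L, 4L)$mp
  crep <- qc_check(clean, allowed_relations = eq_relations())
  expect_identical(length(crep$missing_definitions), 0L)
  expect_identical(nrow(crep$synonym_equals_label), 0L)
  expect_identical(nrow(crep$duplicate_synonyms_within_term), 0L)
  expect_identical(nrow(crep$shared_exact_synonyms), 0L)
  expect_identical(nrow(crep$invalid_relations), 0L)
})

test_that("invalid EQ relations are reported when an allow-list is given", {
  onto <- ontology("MP", list(
    pheno_term("MP:0000001", "strange def",
               definition = "Uses a relation outside the allow-list.",
               logical_def = eq_expression("PATO:0000051", list(
                 list(relation = "part_of", filler = "UBERON:0000001")),
                 allowed_relations = NULL))))
  rep <- qc_check(onto, allowed_relations = eq_relations())
  expect_identical(rep$invalid_relations$term_id, "MP:0000001")
  expect_identical(rep$invalid_relations$relation, "part_of")
  expect_identical(nrow(qc_check(onto)$invalid_relations), 0L)
})

test_that("fixture generation is deterministic and honors the empty case", {
  a <- generate_fixture_pair(1L, 2L, 6L)
  b <- generate_fixture_pair(1L, 2L, 6L)
  expect_identical(write_obo(a$mp), write_obo(b$mp))
  expect_identical(write_obo(a$hp), write_obo(b$hp))
  expect_identical(write_sssom(a$truth), write_sssom(b$truth))

  z <- generate_fixture_pair(1L, 0L, 0L)
  expect_identical(length(z$mp$terms), 0L)
  expect_identical(length(z$hp$terms), 0L)
  expect_identical(nrow(z$truth$mappings), 0L)
})

test_that("dangling parents are reported, not errors", {
  onto <- parse_obo(c("[Term]", "id: MP:0000002", "name: child",
                      "is_a: MP:0000001"))
  expect_identical(dangling_parents(onto), "MP:0000001")
})
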