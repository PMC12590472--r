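test_that("merge keeps the best method, then the best predicate", {
  manual_rel <- mapping_set(mk_mapping_row("MP:0000001", "HP:0000001",
                                           "skos:relatedMatch"))
  lex_exact <- mapping_set(mk_mapping_row("MP:0000001", "HP:0000001",
                                          "skos:exactMatch", method = "lexical"))
  out <- merge_mappings(list(manual_rel, lex_exact))$mappings
  expect_identical(nrow(out), 1L)
  expect_identical(out$method, "manual")
  expect_identical(out$predicate_id, "skos:relatedMatch")
  expect_match(out$comment, "superseded: lexical skos:exactMatch", fixed = TRUE)

  two_lex <- mapping_set(rbind(
    mk_mapping_row("MP:0000001", "HP:0000001", "skos:exactMatch", method = "lexical"),
    mk_mapping_row("MP:0000001", "HP:0000001", "skos:narrowMatch", method = "lexical")))
  out2 <- merge_mappings(list(two_lex))$mappings
  expect_identical(out2$predicate_id, "skos:exactMatch")

  expect_identical(nrow(merge_mappings(list(mapping_set()))$mappings), 0L)
})

test_that("merge respects priority for every method/predicate combination", {
  methods <- c("manual", "logical", "lexical")
  preds <- skos_predicates()
  policy <- merge_policy()
  for (m1 in methods) for (p1 in preds) for (m2 in methods) for (p2 in preds) {
    s1 <- mapping_set(mk_mapping_row("MP:0000009", "HP:0000009", p1, method = m1))
    s2 <- mapping_set(mk_mapping_row("MP:0000009", "HP:0000009", p2, method = m2))
    out <- merge_mappings(list(s1, s2), policy)$mappings
    expect_identical(nrow(out), 1L)
    r1 <- match(m1, policy$method_priority)
    r2 <- match(m2, policy$method_priority)
    if (r1 != r2) {
      expect_identical(out$method, if (r1 < r2) m1 else m2)
    } else {
      q1 <- match(p1, policy$predicate_priority)
      q2 <- match(p2, policy$predicate_priority)
      expect_identical(out$predicate_id, if (q1 <= q2) p1 else p2)
    }
  }
})

test_that("merge is idempotent, order-invariant and never invents rows", {
  withr::with_seed(71L, {
    for (i in 1:100) {
      sets <- list(rand_mapping_set("manual"), rand_mapping_set("logical"),
                   rand_mapping_set("lexical"))
      merged <- merge_mappings(sets)
      expect_identical(merge_mappings(list(merged))$mappings, merged$mappings)
      for (perm in list(c(2L, 1L, 3L), c(3L, 2L, 1L), c(2L, 3L, 1L))) {
        expect_identical(merge_mappings(sets[perm])$mappings, merged$mappings)
      }
      pool <- do.call(rbind, lapply(sets, function(s) s$mappings))
      pool_key <- paste(pool$subject_id, pool$object_id, pool$predicate_id,
                        pool$method)
      out_key <- paste(merged$mappings$subject_id, merged$mappings$object_id,
                       merged$mappings$predicate_id, merged$mappings$method)
      expect_true(all(out_key %in% pool_key))
      expect_identical(anyDuplicated(paste(merged$mappings$subject_id,
                                           merged$mappings$object_id)), 0L)
    }
  })
})

test_that("exact-without-logical-agreement report finds planted disagreements", {
  fx <- anophthalmia_fixture(fixed = FALSE)
  rep <- report_exact_without_logical_agreement(fx$manual, fx$mp, fx$hp)
  expect_identical(nrow(rep$items), 1L)
  expect_identical(rep$items$detail, "logical definitions differ")
  fx2 <- anophthalmia_fixture(fixed = TRUE)
  rep2 <- report_exact_without_logical_agreement(fx2$manual, fx2$mp, fx2$hp)
  expect_identical(nrow(rep2$items), 0L)

  # planted-count oracle: k disagreeing + k agreeing exact pairs
  withr::with_seed(81L, {
    for (k in c(0L, 3L, 7L)) {
      n <- k + 4L
      eqs <- lapply(seq_len(n), function(i)
        eq_expression("PATO:0000051", list(
          list(relation = "characteristic_of_part_of",
               filler = sprintf("UBERON:%07d", i)))))
      mp_terms <- lapply(seq_len(n), function(i)
        pheno_term(sprintf("MP:%07d", i), paste("mp term", i),
                   definition = "d", logical_def = eqs[[i]]))
      disagree <- sample.int(n, k)
      hp_terms <- lapply(seq_len(n), function(i) {
        eq <- if (i %in% disagree) {
          eq_expression("PATO:0000051", list(
            list(relation = "characteristic_of",
                 filler = sprintf("UBERON:%07d", i))))
        } else {
          eqs[[i]]
        }
        pheno_term(sprintf("HP:%07d", i), paste("hp term", i),
                   definition = "d", logical_def = eq)
      })
      manual <- mapping_set(do.call(rbind, lapply(seq_len(n), function(i)
        mk_mapping_row(sprintf("MP:%07d", i), sprintf("HP:%07d", i),
                       "skos:exactMatch"))))
      rep <- report_exact_without_logical_agreement(
        manual, ontology("MP", mp_terms), ontology("HP", hp_terms))
      expect_identical(nrow(rep$items), k)
      expect_setequal(rep$items$subject_id, sprintf("MP:%07d", disagree))
    }
  })
})

test_that("logical-without-exact report flags non-exact manual mappings", {
  fx <- polycystic_fixture()
  rep <- report_logical_without_exact_mapping(fx$manual, fx$mp, fx$hp)
  expect_identical(nrow(rep$items), 1L)
  expect_match(rep$items$detail, "skos:narrowMatch")

  exact_manual <- mapping_set(mk_mapping_row("MP:0008528", "HP:0000113",
                                             "skos:exactMatch"))
  expect_identical(
    nrow(report_logical_without_exact_mapping(exact_manual, fx$mp, fx$hp)$items),
    0L)

  unmapped <- mapping_set()
  rep3 <- report_logical_without_exact_mapping(unmapped, fx$mp, fx$hp)
  expect_identical(rep3$items$detail, "pair not manually mapped")
})

test_that("multi-exact report lists ambiguous subjects and objects", {
  fx <- osteopenia_fixture("exact")
  rep <- report_multi_exact_lexical(lexical_match(fx$mp, fx$hp))
  expect_identical(nrow(rep$items), 1L)
  expect_identical(rep$items$id, "MP:0000063")
  expect_identical(rep$items$partners, "HP:0000938|HP:0004349")

  # injective planted fixture has no multi-exact findings
  fx2 <- generate_fixture_pair(61L, 2L, 5L)
  rep2 <- report_multi_exact_lexical(lexical_match(fx2$mp, fx2$hp))
  expect_identical(nrow(rep2$items), 0L)

  # planted-count oracle on the object side
  hp_shared <- ontology("HP", list(
    pheno_term("HP:0000001", "Shared label", definition = "d")))
  mp_two <- ontology("MP", list(
    pheno_term("MP:0000001", "shared label", definition = "d"),
    pheno_term("MP:0000002", "other name", definition = "d",
               synonyms = list(synonym("shared label", "exact")))))
  rep3 <- report_multi_exact_lexical(lexical_match(mp_two, hp_shared))
  expect_identical(rep3$items$id, "HP:0000001")
  expect_identical(rep3$items$side, "object")
})
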