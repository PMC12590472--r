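# Worked-example fixtures and small builders shared across test files.

mk_mapping_row <- function(s, o, pred, method = "manual", slab = "",
                           olab = "", comment = "", author = "",
                           date = "") {
  data.frame(subject_id = s, subject_label = slab, predicate_id = pred,
             object_id = o, object_label = olab, method = method,
             author_id = author, mapping_date = date, comment = comment,
             stringsAsFactors = FALSE)
}

# MP 'decreased bone mineral density' vs HP 'Osteopenia' and
# 'Reduced bone mineral density'; the osteopenia synonym starts exact and
# can be demoted to narrow.
osteopenia_fixture <- function(osteopenia_scope = "exact") {
  mp <- ontology("MP", list(
    pheno_term("MP:0000063", "decreased bone mineral density",
               definition = "Reduction in bone mineral per unit area.",
               synonyms = list(synonym("osteopenia", osteopenia_scope),
                               synonym("reduced bone mineral density", "exact")))
  ))
  hp <- ontology("HP", list(
    pheno_term("HP:0000938", "Osteopenia",
               definition = "Mild reduction of bone mineral density."),
    pheno_term("HP:0004349", "Reduced bone mineral density",
               definition = "Reduction of bone mineral density.")
  ))
  list(mp = mp, hp = hp)
}

# Labels 'hypospadia' vs 'Hypospadias' differ as token bags; the pair is
# related only through a curated narrowMatch.
hypospadias_fixture <- function() {
  mp <- ontology("MP", list(
    pheno_term("MP:0003124", "hypospadia",
               definition = "Urethral opening on the ventral surface, either sex.")
  ))
  hp <- ontology("HP", list(
    pheno_term("HP:0000047", "Hypospadias",
               definition = "Male urethral meatus on the ventral penile shaft.")
  ))
  manual <- mapping_set(
    mk_mapping_row("MP:0003124", "HP:0000047", "skos:narrowMatch",
                   slab = "hypospadia", olab = "Hypospadias",
                   comment = "HP term male-specific"),
    subject_prefix = "MP", object_prefix = "HP")
  list(mp = mp, hp = hp, manual = manual)
}

# Exact manual mapping whose anatomical filler disagrees until the MP side
# is switched from camera-type eye to eyeball of camera-type eye.
anophthalmia_fixture <- function(fixed = FALSE) {
  filler <- if (fixed) "UBERON:0010230" else "UBERON:0000019"
  eq_mp <- eq_expression("PATO:0000462", list(
    list(relation = "towards", filler = filler),
    list(relation = "has_modifier", filler = "PATO:0000460")))
  eq_hp <- eq_expression("PATO:0000462", list(
    list(relation = "towards", filler = "UBERON:0010230"),
    list(relation = "has_modifier", filler = "PATO:0000460")))
  mp <- ontology("MP", list(
    pheno_term("MP:0001293", "anophthalmia",
               definition = "Absence of the eye.", logical_def = eq_mp)
  ))
  hp <- ontology("HP", list(
    pheno_term("HP:0000528", "Anophthalmia",
               definition = "Absence of the eyeball.", logical_def = eq_hp)
  ))
  manual <- mapping_set(
    mk_mapping_row("MP:0001293", "HP:0000528", "skos:exactMatch",
                   slab = "anophthalmia", olab = "Anophthalmia"),
    subject_prefix = "MP", object_prefix = "HP")
  list(mp = mp, hp = hp, manual = manual)
}

# Identical logical definitions manually mapped as narrowMatch.
polycystic_fixture <- function() {
  eq <- eq_expression("PATO:0001669", list(
    list(relation = "characteristic_of_part_of", filler = "UBERON:0002113"),
    list(relation = "has_modifier", filler = "PATO:0000460")))
  mp <- ontology("MP", list(
    pheno_term("MP:0008528", "polycystic kidney",
               definition = "Multiple cysts in both kidneys.",
               logical_def = eq)
  ))
  hp <- ontology("HP", list(
    pheno_term("HP:0000113", "Polycystic kidney dysplasia",
               definition = "Multiple cysts in the kidney.",
               logical_def = eq)
  ))
  manual <- mapping_set(
    mk_mapping_row("MP:0008528", "HP:0000113", "skos:narrowMatch",
                   slab = "polycystic kidney",
                   olab = "Polycystic kidney dysplasia",
                   comment = "HP logical definition misses bilaterality"),
    subject_prefix = "MP", object_prefix = "HP")
  list(mp = mp, hp = hp, manual = manual)
}

midface_fixture <- function() {
  ontology("MP", list(
    pheno_term("MP:0009855", "midface retrusion",
               definition = "Posterior positioning of the midface."),
    pheno_term("MP:0012085", "midface hypoplasia",
               definition = "Underdevelopment of the midface.")
  ))
}

morphology_pattern <- function() {
  read_pattern(system.file("extdata", "patterns",
                           "abnormalMorphologyOfPartOfAnatomicalEntity.yaml",
                           package = "phemap"))
}

# random mapping set over a small id pool, one method per set
rand_mapping_set <- function(method, n_max = 6L, pool = 5L) {
  n <- sample.int(n_max, 1L)
  df <- mk_mapping_row(sprintf("MP:%07d", sample.int(pool, n, replace = TRUE)),
                       sprintf("HP:%07d", sample.int(pool, n, replace = TRUE)),
                       sample(skos_predicates(), n, replace = TRUE),
                       method = method)
  mapping_set(df)
}

# random symptom-table rows
rand_symptom_rows <- function(n = 5L) {
  lapply(seq_len(n), function(i) {
    symptom_mapping(paste("symptom", i, sample(letters, 1L)),
                    mp_ids = sprintf("MP:%07d", sample.int(50L, sample(0:3, 1L))),
                    hp_ids = sprintf("HP:%07d", sample.int(50L, sample(0:3, 1L))),
                    source_refs = paste0("PMID:", sample.int(99999L, sample(0:2, 1L))))
  })
}

# seeded fault injection for the QC oracle; returns the corrupted
# ontology.  Faults are planted on disjoint term sets so each category's
# finding count equals its injection count.
inject_qc_faults <- function(onto, k_missing, k_shared, k_label_syn) {
  ids <- names(Filter(function(t) !t$deprecated, onto$terms))
  stopifnot(length(ids) >= k_missing + 2L * k_shared + k_label_syn)
  picks <- sample(ids, k_missing + 2L * k_shared + k_label_syn)
  miss <- picks[seq_len(k_missing)]
  shared <- picks[k_missing + seq_len(2L * k_shared)]
  lab <- picks[k_missing + 2L * k_shared + seq_len(k_label_syn)]
  for (id in miss) onto$terms[[id]]["definition"] <- list(NULL)
  for (j in seq_len(k_shared)) {
    txt <- paste("planted shared synonym", j)
    for (id in shared[c(2L * j - 1L, 2L * j)]) {
      t <- onto$terms[[id]]
      t$synonyms <- c(t$synonyms, list(synonym(txt, "exact")))
      onto$terms[[id]] <- t
    }
  }
  for (id in lab) {
    t <- onto$terms[[id]]
    t$synonyms <- c(t$synonyms, list(synonym(t$label, "exact")))
    onto$terms[[id]] <- t
  }
  onto
}

spo <- function(set) {
  df <- set$mappings[, c("subject_id", "predicate_id", "object_id")]
  df <- df[order(df$subject_id, df$object_id, df$predicate_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
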