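# Seeded generator of paired mini-ontologies with planted ground-truth
# mappings.  The vocabulary is a fixed built-in word list so that decoy
# terms can be built as controlled near-misses: sharing at least one
# token with a planted label but never a full token bag.

fixture_vocab <- function() {
  c(# anatomical nouns
    "femur", "tibia", "fibula", "humerus", "radius", "ulna", "cranium",
    "mandible", "maxilla", "palate", "lip", "kidney", "liver", "spleen",
    "heart", "lung", "retina", "cornea", "lens", "iris", "cochlea",
    "sternum", "rib", "vertebra", "scapula", "pelvis", "ileum", "jejunum",
    "colon", "stomach", "pancreas", "thymus", "thyroid", "adrenal",
    "ovary", "testis", "uterus", "bladder", "urethra", "aorta", "artery",
    "vein", "capillary", "neuron", "axon", "dendrite", "myelin", "cortex",
    "cerebellum", "hippocampus", "striatum", "tongue", "tooth", "enamel",
    "dentin", "follicle", "epidermis", "dermis", "claw", "tail", "snout",
    "whisker", "forelimb", "hindlimb", "autopod", "digit", "phalanx",
    "muscle", "tendon", "ligament", "cartilage", "marrow",
    # qualities
    "increased", "decreased", "abnormal", "absent", "enlarged", "reduced",
    "elongated", "shortened", "thickened", "thinned", "dilated",
    "constricted", "fragmented", "fused", "duplicated", "ectopic",
    "hypoplastic", "hyperplastic", "degenerate", "cystic", "fibrotic",
    "necrotic", "inflamed", "pale", "pigmented", "translucent", "curved",
    "bent", "twisted", "ruptured",
    # attribute nouns
    "size", "length", "width", "density", "volume", "number", "count",
    "mass", "weight", "morphology", "structure", "orientation",
    "position", "spacing", "texture", "tone", "level", "concentration",
    "pressure", "temperature", "rate", "rhythm", "amplitude", "latency",
    "threshold", "sensitivity", "motility", "adhesion", "proliferation",
    "differentiation", "migration", "apoptosis", "regeneration",
    "ossification", "mineralization", "vascularization", "innervation")
}

capitalize <- function(x) {
  paste0(toupper(substring(x, 1L, 1L)), substring(x, 2L))
}

#' Generate a paired MP-like / HP-like fixture with planted mappings
#'
#' Builds two mini-ontologies plus the ground-truth [mapping_set()] the
#' lexical matcher should recover.  For every cell of the synonym-scope
#' match matrix -- every combination of subject field and object field in
#' label/exact/narrow/broad/related -- it plants `n_planted_per_cell`
#' term pairs whose match arises exactly from that cell: the match text
#' sits in the stated field on each side (word order permuted and the
#' HP-side text capitalized, exercising token-bag normalization) and all
#' other labels are globally unique token bags.  Decoy terms share at
#' least one token with some planted label but never a full bag, so a
#' correct matcher must never match them.  Every term gets a text
#' definition so a fresh fixture is QC-clean.  Output is deterministic
#' for a fixed seed.
#'
#' @param seed integer seed.
#' @param n_planted_per_cell pairs planted per matrix cell (>= 0).
#' @param n_decoys number of decoy terms, alternating between the two
#'   ontologies (>= 0).
#' @return list with elements `mp`, `hp` (ontologies) and `truth` (the
#'   planted [mapping_set()]).
#' @export
generate_fixture_pair <- function(seed, n_planted_per_cell = 3L,
                                  n_decoys = 0L) {
  stopifnot(n_planted_per_cell >= 0L, n_decoys >= 0L)
  withr::with_seed(seed, {
    vocab <- fixture_vocab()
    used <- new.env(parent = emptyenv())
    draw_bag <- function() {
      repeat {
        w <- sample(vocab, sample(2:4, 1L))
        key <- bag_key(sort(w))
        if (is.null(used[[key]])) {
          used[[key]] <- TRUE
          return(w)
        }
      }
    }
    fields <- match_fields()
    mp_terms <- list(); hp_terms <- list()
    truth_rows <- list()
    planted_bags <- list()
    mp_i <- 0L; hp_i <- 0L

    mk_term <- function(id, label, match_text, field) {
      syns <- if (field == "label") list() else
        list(synonym(match_text, field))
      lab <- if (field == "label") match_text else label
      pheno_term(id, lab,
                 definition = paste0("Synthetic phenotype: ", lab, "."),
                 synonyms = syns)
    }

    for (sf in fields) {
      for (of in fields) {
        for (k in seq_len(n_planted_per_cell)) {
          w <- draw_bag()
          planted_bags[[length(planted_bags) + 1L]] <- w
          mp_text <- paste(w, collapse = " ")
          hp_text <- capitalize(paste(sample(w), collapse = " "))
          mp_i <- mp_i + 1L; hp_i <- hp_i + 1L
          mp_id <- sprintf("MP:%07d", mp_i)
          hp_id <- sprintf("HP:%07d", hp_i)
          mp_filler <- paste(draw_bag(), collapse = " ")
          hp_filler <- capitalize(paste(draw_bag(), collapse = " "))
          mp_terms[[length(mp_terms) + 1L]] <-
            mk_term(mp_id, mp_filler, mp_text, sf)
          hp_terms[[length(hp_terms) + 1L]] <-
            mk_term(hp_id, hp_filler, hp_text, of)
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            subject_id = mp_id,
            subject_label = if (sf == "label") mp_text else mp_filler,
            predicate_id = classify_pair(sf, of),
            object_id = hp_id,
            object_label = if (of == "label") hp_text else hp_filler,
            method = "lexical", author_id = "", mapping_date = "",
            comment = "", stringsAsFactors = FALSE)
        }
      }
    }

    for (j in seq_len(n_decoys)) {
      repeat {
        base <- if (length(planted_bags)) {
          planted_bags[[sample.int(length(planted_bags), 1L)]]
        } else {
          sample(vocab, 2L)
        }
        keep <- if (length(base) > 1L) {
          sample(base, length(base) - 1L)
        } else {
          base
        }
        extra <- sample(setdiff(vocab, base), sample(1:2, 1L))
        w <- c(keep, extra)
        key <- bag_key(sort(w))
        if (is.null(used[[key]])) {
          used[[key]] <- TRUE
          break
        }
      }
      lab <- paste(w, collapse = " ")
      if (j %% 2L == 1L) {
        mp_i <- mp_i + 1L
        mp_terms[[length(mp_terms) + 1L]] <- pheno_term(
          sprintf("MP:%07d", mp_i), lab,
          definition = paste0("Synthetic decoy phenotype: ", lab, "."))
      } else {
        hp_i <- hp_i + 1L
        hp_terms[[length(hp_terms) + 1L]] <- pheno_term(
          sprintf("HP:%07d", hp_i), capitalize(lab),
          definition = paste0("Synthetic decoy phenotype: ", lab, "."))
      }
    }

    truth_df <- if (length(truth_rows)) {
      do.call(rbind, truth_rows)
    } else {
      empty_mappings()
    }
    truth_df <- truth_df[order(truth_df$subject_id, truth_df$object_id), ,
                         drop = FALSE]
    rownames(truth_df) <- NULL
    list(mp = ontology("MP", mp_terms),
         hp = ontology("HP", hp_terms),
         truth = mapping_set(truth_df,
                             metadata = list(
                               mapping_set_id = paste0("fixture-seed-", seed)),
                             subject_prefix = "MP", object_prefix = "HP"))
  })
}
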