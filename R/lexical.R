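# Token-bag lexical matcher with synonym-scope -> SKOS predicate matrix.

match_fields <- function() c("label", "exact", "narrow", "broad", "related")

#' Classify a lexical hit by the synonym-scope matrix
#'
#' Given the field an MP-side string came from (the term label or a
#' synonym of some scope) and the field of the matching HP-side string,
#' returns the SKOS mapping predicate for the hit.  Labels and exact
#' synonyms are interchangeable: label-label, label-exact and exact-exact
#' hits are all `skos:exactMatch`.  An MP narrow synonym against an HP
#' label/exact synonym is `skos:narrowMatch` (the HP term is the narrower
#' concept), and symmetrically an MP broad synonym -- or an HP narrow
#' synonym -- yields `skos:broadMatch`; an HP broad synonym yields
#' `skos:narrowMatch`.  Any hit involving a related synonym, or two
#' non-exact scopes, degrades to `skos:relatedMatch`.  `skos:closeMatch`
#' is reserved for manual curation and never produced lexically.
#'
#' @param subject_field,object_field one of `"label"`, `"exact"`,
#'   `"narrow"`, `"broad"`, `"related"`.
#' @return a SKOS predicate CURIE.
#' @examples
#' classify_pair("label", "label")   # skos:exactMatch
#' classify_pair("narrow", "label")  # skos:narrowMatch
#' classify_pair("exact", "narrow")  # skos:broadMatch
#' @export
classify_pair <- function(subject_field, object_field) {
  subject_field <- match.arg(subject_field, match_fields())
  object_field <- match.arg(object_field, match_fields())
  s <- if (subject_field %in% c("label", "exact")) "L" else subject_field
  o <- if (object_field %in% c("label", "exact")) "L" else object_field
  if (s == "related" || o == "related") return("skos:relatedMatch")
  if (s == "L" && o == "L") return("skos:exactMatch")
  if (s == "narrow" && o == "L") return("skos:narrowMatch")
  if (s == "L" && o == "broad") return("skos:narrowMatch")
  if (s == "broad" && o == "L") return("skos:broadMatch")
  if (s == "L" && o == "narrow") return("skos:broadMatch")
  "skos:relatedMatch"
}

# one row per matchable string of each non-deprecated term
term_entries <- function(onto) {
  rows <- lapply(onto$terms, function(t) {
    if (t$deprecated) return(NULL)
    txt <- c(t$label, vapply(t$synonyms, function(s) s$text, ""))
    fld <- c("label", vapply(t$synonyms, function(s) s$scope, ""))
    data.frame(id = t$id, label = t$label, field = fld, text = txt,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(id = character(), label = character(),
                      field = character(), text = character(),
                      key = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df$key <- label_keys(df$text)
  df[nzchar(df$key), , drop = FALSE]
}

#' Generate lexical mappings between two ontologies
#'
#' Compares every label and synonym of every non-deprecated MP-side term
#' against those of every non-deprecated HP-side term; a hit is called
#' when the full token bags are equal ([normalize_label()]), i.e. when all
#' the words match regardless of order, case and punctuation.  Each hit is
#' classified via [classify_pair()]; multiple hits for the same
#' `(subject, object)` pair collapse to one mapping keeping the
#' highest-priority predicate (exact > narrow > broad > related).  The
#' winning matched strings and field pair are recorded in the mapping
#' comment.
#'
#' @param mp subject-side ontology (mouse).
#' @param hp object-side ontology (human).
#' @return a [mapping_set()] with `method = "lexical"`.
#' @export
lexical_match <- function(mp, hp) {
  stopifnot(inherits(mp, "pheno_ontology"), inherits(hp, "pheno_ontology"))
  a <- term_entries(mp)
  b <- term_entries(hp)
  m <- merge(a, b, by = "key", suffixes = c(".s", ".o"))
  if (!nrow(m)) {
    return(mapping_set(metadata = list()))
  }
  m$predicate_id <- mapply(classify_pair, m$field.s, m$field.o,
                           USE.NAMES = FALSE)
  pred_rank <- match(m$predicate_id,
                     c("skos:exactMatch", "skos:narrowMatch",
                       "skos:broadMatch", "skos:relatedMatch"))
  fr_s <- match(m$field.s, match_fields())
  fr_o <- match(m$field.o, match_fields())
  ord <- order(m$id.s, m$id.o, pred_rank, fr_s, fr_o, m$text.s, m$text.o)
  m <- m[ord, , drop = FALSE]
  m <- m[!duplicated(paste(m$id.s, m$id.o, sep = "\r")), , drop = FALSE]

  df <- data.frame(
    subject_id = m$id.s, subject_label = m$label.s,
    predicate_id = m$predicate_id,
    object_id = m$id.o, object_label = m$label.o,
    method = "lexical", author_id = "", mapping_date = "",
    comment = paste0("match: '", m$text.s, "' ~ '", m$text.o, "' (",
                     m$field.s, "-", m$field.o, ")"),
    stringsAsFactors = FALSE)
  mapping_set(df, subject_prefix = mp$prefix, object_prefix = hp$prefix)
}
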