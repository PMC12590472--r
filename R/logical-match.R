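#' Match terms across ontologies by identical logical definitions
#'
#' One mapping per (MP term, HP term) pair whose EQ logical definitions
#' are identical under [eq_equal()]; terms lacking a logical definition
#' and deprecated terms are skipped.  All hits are `skos:exactMatch` with
#' `method = "logical"`: identity of logical definitions asserts identity
#' of meaning as far as the definitions go, even when manual curation
#' disagrees (such pairs are surfaced downstream by
#' [report_logical_without_exact_mapping()]).
#'
#' @param mp subject-side ontology (mouse).
#' @param hp object-side ontology (human).
#' @return a [mapping_set()] with `method = "logical"`.
#' @export
logical_match <- function(mp, hp) {
  stopifnot(inherits(mp, "pheno_ontology"), inherits(hp, "pheno_ontology"))
  take <- function(onto) {
    keep <- Filter(function(t) !t$deprecated && !is.null(t$logical_def),
                   onto$terms)
    data.frame(id = vapply(keep, function(t) t$id, ""),
               label = vapply(keep, function(t) t$label, ""),
               key = vapply(keep, function(t) eq_key(t$logical_def), ""),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  a <- take(mp)
  b <- take(hp)
  m <- merge(a, b, by = "key", suffixes = c(".s", ".o"))
  m <- m[order(m$id.s, m$id.o), , drop = FALSE]
  if (!nrow(m)) return(mapping_set())
  df <- data.frame(
    subject_id = m$id.s, subject_label = m$label.s,
    predicate_id = "skos:exactMatch",
    object_id = m$id.o, object_label = m$label.o,
    method = "logical", author_id = "", mapping_date = "",
    comment = "identical logical definitions",
    stringsAsFactors = FALSE)
  mapping_set(df, subject_prefix = mp$prefix, object_prefix = hp$prefix)
}
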