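#' Obsolete (deprecate) a term, optionally merging it into another
#'
#' Deprecation never deletes an id: the victim stays in the ontology with
#' `deprecated = TRUE`, its logical definition and parents removed and,
#' when a merge target is given, `replaced_by` pointing at it.  When
#' merging, the victim's primary label is added to the target as an exact
#' synonym, the standard way a merged term remains findable (e.g. merging
#' "midface retrusion" into "midface hypoplasia" leaves the hypoplasia
#' term carrying "midface retrusion" as an exact synonym).
#'
#' @param onto a [ontology()] object.
#' @param victim CURIE of the term to deprecate; must exist and not
#'   already be deprecated.
#' @param merge_into optional CURIE of the replacement term; must exist,
#'   be distinct from `victim` and not be deprecated.
#' @return the modified ontology.
#' @export
obsolete_term <- function(onto, victim, merge_into = NULL) {
  stopifnot(inherits(onto, "pheno_ontology"))
  t <- onto$terms[[victim]]
  if (is.null(t)) stop("unknown term: ", victim)
  if (t$deprecated) stop("term already deprecated: ", victim)
  if (!is.null(merge_into)) {
    if (identical(merge_into, victim)) {
      stop("cannot merge a term into itself: ", victim)
    }
    tgt <- onto$terms[[merge_into]]
    if (is.null(tgt)) stop("unknown merge target: ", merge_into)
    if (tgt$deprecated) stop("merge target is deprecated: ", merge_into)
    tgt$synonyms <- c(tgt$synonyms, list(synonym(t$label, "exact")))
    onto$terms[[merge_into]] <- tgt
  }
  t$deprecated <- TRUE
  t["logical_def"] <- list(NULL)
  t$parents <- character()
  t["replaced_by"] <- list(merge_into)
  onto$terms[[victim]] <- t
  onto
}
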