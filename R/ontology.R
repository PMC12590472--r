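#' Construct a scoped synonym
#'
#' @param text synonym text (non-empty).
#' @param scope one of `"exact"`, `"narrow"`, `"broad"`, `"related"` --
#'   the OBO synonym scope, which states how the synonym's meaning relates
#'   to the term's and drives the SKOS predicate chosen by
#'   [classify_pair()].
#' @return a list with elements `text` and `scope`.
#' @export
synonym <- function(text, scope = c("exact", "narrow", "broad", "related")) {
  scope <- match.arg(scope)
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  list(text = text, scope = scope)
}

#' Construct an ontology term
#'
#' One ontology class: CURIE id, primary label, optional text definition,
#' scoped synonyms, `is_a` parents, an optional EQ logical definition,
#' deprecation state and provenance metadata.  Deprecated terms carry no
#' logical definition and only deprecated terms may point at a
#' `replaced_by` successor.  Logical definitions are stored in canonical
#' form (see [canonicalize_eq()]).
#'
#' @param id CURIE, e.g. `"MP:0003124"`.
#' @param label primary label (without any `"obsolete "` prefix).
#' @param definition text definition or `NULL`.
#' @param synonyms list of [synonym()] objects.
#' @param parents character vector of parent CURIEs.
#' @param logical_def an [eq_expression()] or `NULL`.
#' @param deprecated logical; deprecated terms are never deleted, their id
#'   persists in the ontology.
#' @param replaced_by CURIE of the replacement term, only for deprecated
#'   terms, or `NULL`.
#' @param contributors character vector of ORCID iDs.
#' @param creation_date ISO-8601 dateTime string or `NULL`.
#' @param other character vector of raw tag-value lines preserved opaquely
#'   for round-tripping.
#' @return an object of class `pheno_term`.
#' @export
pheno_term <- function(id, label, definition = NULL, synonyms = list(),
                       parents = character(), logical_def = NULL,
                       deprecated = FALSE, replaced_by = NULL,
                       contributors = character(), creation_date = NULL,
                       other = character()) {
  stopifnot(is.character(id), length(id) == 1L, grepl(":", id, fixed = TRUE),
            is.character(label), length(label) == 1L,
            is.logical(deprecated), length(deprecated) == 1L)
  if (!is.null(definition)) {
    stopifnot(is.character(definition), length(definition) == 1L)
  }
  if (deprecated && !is.null(logical_def)) {
    stop("deprecated term ", id, " must not carry a logical definition")
  }
  if (!is.null(replaced_by) && !deprecated) {
    stop("replaced_by is only valid on a deprecated term (", id, ")")
  }
  if (!is.null(logical_def)) {
    stopifnot(inherits(logical_def, "eq_expression"))
    logical_def <- canonicalize_eq(logical_def)
  }
  for (s in synonyms) {
    stopifnot(is.list(s), nzchar(s$text),
              s$scope %in% c("exact", "narrow", "broad", "related"))
  }
  structure(list(id = id, label = label, definition = definition,
                 synonyms = synonyms, parents = as.character(parents),
                 logical_def = logical_def, deprecated = deprecated,
                 replaced_by = replaced_by,
                 contributors = as.character(contributors),
                 creation_date = creation_date,
                 other = as.character(other)),
            class = "pheno_term")
}

#' Construct an ontology
#'
#' An id-indexed collection of [pheno_term()] objects plus the id prefix of
#' the ontology (e.g. `"MP"` or `"HP"`).  Term ids must be unique; no
#' operation in the package ever removes an id (obsoletion flips the
#' deprecation flag instead, see [obsolete_term()]).
#'
#' @param prefix id prefix string.
#' @param terms list of `pheno_term` objects.
#' @param header character vector of extra OBO header lines preserved for
#'   round-tripping.
#' @param extra_stanzas list of character vectors: raw non-`[Term]` stanzas
#'   (e.g. `[Typedef]`) preserved opaquely.
#' @return an object of class `pheno_ontology`.
#' @export
ontology <- function(prefix, terms = list(), header = character(),
                     extra_stanzas = list()) {
  stopifnot(is.character(prefix), length(prefix) == 1L, nzchar(prefix))
  ids <- vapply(terms, function(t) t$id, character(1L))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate term id: ", paste(unique(dup), collapse = ", "))
  names(terms) <- ids
  structure(list(prefix = prefix, terms = terms,
                 header = as.character(header),
                 extra_stanzas = extra_stanzas),
            class = "pheno_ontology")
}

#' Parent CURIEs that do not resolve within the ontology
#'
#' Fragments of large ontologies routinely reference parents outside the
#' fragment, so dangling parents are reported, never treated as errors.
#'
#' @param onto a `pheno_ontology`.
#' @return character vector of unresolved parent CURIEs.
#' @export
dangling_parents <- function(onto) {
  stopifnot(inherits(onto, "pheno_ontology"))
  all_parents <- unique(unlist(lapply(onto$terms, function(t) t$parents)))
  setdiff(all_parents, names(onto$terms))
}

#' @export
print.pheno_ontology <- function(x, ...) {
  n <- length(x$terms)
  ndep <- sum(vapply(x$terms, function(t) t$deprecated, TRUE))
  cat("<pheno_ontology> prefix=", x$prefix, ": ", n, " terms (",
      ndep, " deprecated)\n", sep = "")
  invisible(x)
}

#' @export
print.pheno_term <- function(x, ...) {
  cat("<pheno_term> ", x$id, " '", x$label, "'",
      if (x$deprecated) " [deprecated]" else "", "\n", sep = "")
  if (length(x$synonyms)) {
    for (s in x$synonyms) cat("  synonym (", s$scope, "): ", s$text, "\n", sep = "")
  }
  if (!is.null(x$logical_def)) cat("  EQ: ", format(x$logical_def), "\n", sep = "")
  invisible(x)
}
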