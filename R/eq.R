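#' Relation allow-list for EQ logical definitions
#'
#' The relations a logical definition may use to attach modifiers to its
#' quality genus.  These mirror the Relations Ontology relations used in
#' phenotype EQ definitions; `characteristic_of` and
#' `characteristic_of_part_of` are deliberately distinct identifiers and
#' never compared as equal.
#'
#' @return character vector of relation identifiers.
#' @export
eq_relations <- function() {
  c("characteristic_of", "characteristic_of_part_of", "has_modifier",
    "towards")
}

#' Construct an EQ (entity--quality) logical definition
#'
#' An EQ expression is a quality genus (typically a PATO CURIE such as
#' `PATO:0000051` "morphology") plus a set of `(relation, filler)` modifier
#' pairs, e.g. `characteristic_of_part_of UBERON:0002387` and
#' `has_modifier PATO:0000460`.  Modifiers form a set: duplicates are
#' dropped and order is irrelevant for equality.
#'
#' @param genus CURIE of the quality term.
#' @param modifiers a list of `(relation, filler)` pairs (each a named
#'   list/vector with elements `relation` and `filler`) or a two-column
#'   data frame with those columns.
#' @param allowed_relations relation allow-list; set `NULL` to skip the
#'   check (QC reports unknown relations instead, see [qc_check()]).
#' @return an object of class `eq_expression`.
#' @examples
#' eq_expression("PATO:0000051", list(
#'   list(relation = "characteristic_of_part_of", filler = "UBERON:0002387"),
#'   list(relation = "has_modifier", filler = "PATO:0000460")
#' ))
#' @export
eq_expression <- function(genus, modifiers = list(),
                          allowed_relations = eq_relations()) {
  stopifnot(is.character(genus), length(genus) == 1L, nzchar(genus))
  md <- as_modifier_df(modifiers)
  if (!is.null(allowed_relations)) {
    bad <- setdiff(md$relation, allowed_relations)
    if (length(bad)) {
      stop("relation(s) not in allow-list: ", paste(bad, collapse = ", "))
    }
  }
  md <- unique(md)
  rownames(md) <- NULL
  structure(list(genus = genus, modifiers = md), class = "eq_expression")
}

as_modifier_df <- function(modifiers) {
  if (is.data.frame(modifiers)) {
    return(data.frame(relation = as.character(modifiers$relation),
                      filler = as.character(modifiers$filler),
                      stringsAsFactors = FALSE))
  }
  if (!length(modifiers)) {
    return(data.frame(relation = character(), filler = character(),
                      stringsAsFactors = FALSE))
  }
  rel <- vapply(modifiers, function(m) as.character(m[["relation"]]), "")
  fil <- vapply(modifiers, function(m) as.character(m[["filler"]]), "")
  data.frame(relation = rel, filler = fil, stringsAsFactors = FALSE)
}

#' Canonicalize an EQ expression
#'
#' Sorts the modifier set lexicographically by `(relation, filler)` and
#' drops duplicates, so that two expressions describing the same definition
#' compare identical.  Idempotent.
#'
#' @param eq an `eq_expression`.
#' @return the canonical `eq_expression`.
#' @export
canonicalize_eq <- function(eq) {
  stopifnot(inherits(eq, "eq_expression"))
  md <- unique(eq$modifiers)
  md <- md[order(md$relation, md$filler), , drop = FALSE]
  rownames(md) <- NULL
  structure(list(genus = eq$genus, modifiers = md), class = "eq_expression")
}

#' Compare two EQ logical definitions
#'
#' True iff the canonical forms are identical: same genus and the same
#' modifier set.  Relations are opaque identifiers, so
#' `characteristic_of` versus `characteristic_of_part_of` (or a different
#' anatomical filler) makes the definitions unequal.  `NULL` on either
#' side (no logical definition) is never equal to anything.
#'
#' @param a,b `eq_expression` objects or `NULL`.
#' @return logical scalar.
#' @export
eq_equal <- function(a, b) {
  if (is.null(a) || is.null(b)) return(FALSE)
  ca <- canonicalize_eq(a)
  cb <- canonicalize_eq(b)
  identical(ca$genus, cb$genus) &&
    identical(ca$modifiers$relation, cb$modifiers$relation) &&
    identical(ca$modifiers$filler, cb$modifiers$filler)
}

# stable string key of the canonical form (used to index logical matches)
eq_key <- function(eq) {
  cc <- canonicalize_eq(eq)
  paste(cc$genus,
        paste(cc$modifiers$relation, cc$modifiers$filler,
              sep = " ", collapse = ";"),
        sep = "|")
}

#' @export
print.eq_expression <- function(x, ...) {
  mods <- paste(x$modifiers$relation, "some", x$modifiers$filler,
                collapse = " and ")
  cat("<eq_expression> ", x$genus,
      if (nrow(x$modifiers)) paste(" and", mods) else "", "\n", sep = "")
  invisible(x)
}

#' @export
format.eq_expression <- function(x, ...) {
  paste0(x$genus,
         if (nrow(x$modifiers)) {
           paste0(" + ", paste(x$modifiers$relation, x$modifiers$filler,
                               collapse = ", "))
         } else "")
}
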