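#' Construct a merge policy
#'
#' Priority rules for collapsing a pair of terms matched by several
#' methods and/or predicates to a single displayed mapping: the method
#' order is manual > logical > lexical, and within the winning method the
#' predicate order is exact > narrow > broad > close > related.
#' `skos:closeMatch` sits between broad and related: directional matches
#' carry more information than close, and close more than related.
#'
#' @param method_priority permutation of `c("manual","logical","lexical")`,
#'   best first.
#' @param predicate_priority permutation of [skos_predicates()], best
#'   first.
#' @return an object of class `merge_policy`.
#' @export
merge_policy <- function(method_priority = c("manual", "logical", "lexical"),
                         predicate_priority = c("skos:exactMatch",
                                                "skos:narrowMatch",
                                                "skos:broadMatch",
                                                "skos:closeMatch",
                                                "skos:relatedMatch")) {
  if (!setequal(method_priority, c("manual", "logical", "lexical")) ||
      anyDuplicated(method_priority)) {
    stop("method_priority must be a permutation of manual/logical/lexical")
  }
  if (!setequal(predicate_priority, skos_predicates()) ||
      anyDuplicated(predicate_priority)) {
    stop("predicate_priority must be a permutation of the SKOS predicates")
  }
  structure(list(method_priority = method_priority,
                 predicate_priority = predicate_priority),
            class = "merge_policy")
}

#' Merge mapping sets under priority rules
#'
#' Combines any number of mapping sets into one with exactly one mapping
#' per `(subject, object)` pair.  The winner is the row with the
#' best-ranked method, ties broken by predicate rank; losing rows are
#' recorded in the winner's comment.  The merge never invents rows, is
#' idempotent, and is invariant to the order of the input sets.  Pairs
#' present in only one input pass through unchanged.
#'
#' @param sets a list of [mapping_set()] objects (or a single set).
#' @param policy a [merge_policy()].
#' @return the merged [mapping_set()].
#' @export
merge_mappings <- function(sets, policy = merge_policy()) {
  if (inherits(sets, "mapping_set")) sets <- list(sets)
  stopifnot(all(vapply(sets, inherits, TRUE, "mapping_set")),
            inherits(policy, "merge_policy"))
  cols <- sssom_columns()
  all_rows <- do.call(rbind, c(lapply(sets, function(s)
    s$mappings[, cols, drop = FALSE]), list(make.row.names = FALSE)))
  if (is.null(all_rows) || !nrow(all_rows)) return(mapping_set())

  mr <- match(all_rows$method, policy$method_priority)
  pr <- match(all_rows$predicate_id, policy$predicate_priority)
  ord <- order(all_rows$subject_id, all_rows$object_id, mr, pr,
               all_rows$author_id, all_rows$mapping_date, all_rows$comment)
  all_rows <- all_rows[ord, , drop = FALSE]
  key4 <- paste(all_rows$subject_id, all_rows$object_id,
                all_rows$predicate_id, all_rows$method, sep = "\r")
  all_rows <- all_rows[!duplicated(key4), , drop = FALSE]

  pair <- paste(all_rows$subject_id, all_rows$object_id, sep = "\r")
  win <- !duplicated(pair)
  winners <- all_rows[win, , drop = FALSE]
  losers <- all_rows[!win, , drop = FALSE]
  if (nrow(losers)) {
    lp <- paste(losers$subject_id, losers$object_id, sep = "\r")
    desc <- paste(losers$method, losers$predicate_id)
    agg <- tapply(desc, lp, paste, collapse = "; ")
    wk <- paste(winners$subject_id, winners$object_id, sep = "\r")
    add <- unname(agg[wk])
    has <- !is.na(add)
    winners$comment[has] <- ifelse(
      nzchar(winners$comment[has]),
      paste0(winners$comment[has], " | superseded: ", add[has]),
      paste0("superseded: ", add[has]))
  }
  rownames(winners) <- NULL
  mapping_set(winners)
}
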