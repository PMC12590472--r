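#' Run quality-control checks on an ontology
#'
#' Dashboard-style curation checks: terms with no text definition,
#' synonyms equal to the term's own label, duplicated synonyms within a
#' term, exact synonyms shared between distinct terms (e.g. two terms both
#' carrying the exact synonym "decreased PPI"), and -- when an allow-list
#' is supplied -- logical-definition relations outside it.  Text
#' comparisons use the lexical normalizer ([normalize_label()]), so case
#' and punctuation differences do not hide a finding.  Deprecated terms
#' are exempt from every check.  The function reports; it never throws.
#'
#' @param onto a [ontology()] object.
#' @param allowed_relations optional character vector of valid EQ
#'   relations (see [eq_relations()]); when `NULL` the relation check is
#'   skipped.
#' @return an object of class `qc_report` with components
#'   `missing_definitions` (CURIEs), `synonym_equals_label` and
#'   `duplicate_synonyms_within_term` (data frames `term_id`, `synonym`),
#'   `shared_exact_synonyms` (data frame `synonym`, `term_ids`,
#'   pipe-delimited) and `invalid_relations` (data frame `term_id`,
#'   `relation`).
#' @export
qc_check <- function(onto, allowed_relations = NULL) {
  stopifnot(inherits(onto, "pheno_ontology"))
  active <- Filter(function(t) !t$deprecated, onto$terms)

  missing_definitions <- names(active)[vapply(active, function(t) {
    is.null(t$definition) || !nzchar(t$definition)
  }, TRUE)]

  sel_rows <- list(); dup_rows <- list(); inv_rows <- list()
  exact_index <- list()  # normalized text -> list(text, ids)
  for (t in active) {
    if (!length(t$synonyms) && is.null(t$logical_def)) next
    syn_texts <- vapply(t$synonyms, function(s) s$text, character(1L))
    syn_keys <- label_keys(syn_texts)
    lab_key <- label_key(t$label)
    eq_lab <- syn_keys == lab_key & nzchar(syn_keys)
    if (any(eq_lab)) {
      sel_rows[[length(sel_rows) + 1L]] <-
        data.frame(term_id = t$id, synonym = syn_texts[eq_lab],
                   stringsAsFactors = FALSE)
    }
    dup <- duplicated(syn_keys)
    if (any(dup)) {
      dup_rows[[length(dup_rows) + 1L]] <-
        data.frame(term_id = t$id, synonym = unique(syn_texts[dup]),
                   stringsAsFactors = FALSE)
    }
    scopes <- vapply(t$synonyms, function(s) s$scope, character(1L))
    for (j in which(scopes == "exact")) {
      k <- syn_keys[j]
      if (!nzchar(k)) next
      e <- exact_index[[k]]
      if (is.null(e)) e <- list(text = syn_texts[j], ids = character())
      e$ids <- union(e$ids, t$id)
      exact_index[[k]] <- e
    }
    if (!is.null(allowed_relations) && !is.null(t$logical_def)) {
      bad <- setdiff(t$logical_def$modifiers$relation, allowed_relations)
      if (length(bad)) {
        inv_rows[[length(inv_rows) + 1L]] <-
          data.frame(term_id = t$id, relation = bad, stringsAsFactors = FALSE)
      }
    }
  }

  shared <- Filter(function(e) length(e$ids) >= 2L, exact_index)
  shared_df <- if (length(shared)) {
    data.frame(synonym = vapply(shared, function(e) e$text, ""),
               term_ids = vapply(shared, function(e)
                 paste(sort(e$ids), collapse = "|"), ""),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(synonym = character(), term_ids = character(),
               stringsAsFactors = FALSE)
  }
  shared_df <- shared_df[order(shared_df$synonym), , drop = FALSE]
  rownames(shared_df) <- NULL

  bind <- function(rows, empty) {
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  empty2 <- function(a, b) {
    out <- data.frame(x = character(), y = character(), stringsAsFactors = FALSE)
    names(out) <- c(a, b)
    out
  }

  structure(list(
    missing_definitions = missing_definitions,
    synonym_equals_label = bind(sel_rows, empty2("term_id", "synonym")),
    duplicate_synonyms_within_term = bind(dup_rows, empty2("term_id", "synonym")),
    shared_exact_synonyms = shared_df,
    invalid_relations = bind(inv_rows, empty2("term_id", "relation"))
  ), class = "qc_report")
}

#' Flatten a QC report into one-finding-per-row form
#'
#' @param report a `qc_report` from [qc_check()].
#' @return data frame with columns `check_id`, `term_id`, `detail`.
#' @export
qc_findings <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  mk <- function(check, ids, details = rep("", length(ids))) {
    data.frame(check_id = rep(check, length(ids)), term_id = ids,
               detail = details, stringsAsFactors = FALSE)
  }
  rows <- list(
    mk("missing_definition", report$missing_definitions),
    mk("synonym_equals_label", report$synonym_equals_label$term_id,
       report$synonym_equals_label$synonym),
    mk("duplicate_synonym_within_term",
       report$duplicate_synonyms_within_term$term_id,
       report$duplicate_synonyms_within_term$synonym),
    mk("shared_exact_synonym", report$shared_exact_synonyms$term_ids,
       report$shared_exact_synonyms$synonym),
    mk("invalid_relation", report$invalid_relations$term_id,
       report$invalid_relations$relation)
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a QC report as TSV
#'
#' @param report a `qc_report`.
#' @param path output file path.
#' @param header_lines optional `#`-prefixed comment lines to prepend.
#' @return the findings data frame, invisibly.
#' @export
write_qc_tsv <- function(report, path, header_lines = character()) {
  df <- qc_findings(report)
  lines <- c(header_lines,
             paste(names(df), collapse = "\t"),
             do.call(paste, c(df, sep = "\t")))
  writeLines(lines, path)
  invisible(df)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n",
      "  missing definitions:            ", length(x$missing_definitions), "\n",
      "  synonym equals label:           ", nrow(x$synonym_equals_label), "\n",
      "  duplicate synonyms within term: ", nrow(x$duplicate_synonyms_within_term), "\n",
      "  shared exact synonyms:          ", nrow(x$shared_exact_synonyms), "\n",
      "  invalid relations:              ", nrow(x$invalid_relations), "\n", sep = "")
  invisible(x)
}
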