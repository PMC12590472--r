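# Curator discrepancy reports: where manual mappings and logical
# definitions disagree, and where lexical matching is ambiguous.

discrepancy_report <- function(kind, items) {
  structure(list(kind = kind, items = items), class = "discrepancy_report")
}

#' @export
print.discrepancy_report <- function(x, ...) {
  cat("<discrepancy_report> ", x$kind, ": ", nrow(x$items), " item(s)\n",
      sep = "")
  invisible(x)
}

#' Report exact manual mappings whose logical definitions disagree
#'
#' Extracts every manually curated `skos:exactMatch` pair whose two terms
#' either lack a logical definition on at least one side or carry
#' differing logical definitions ([eq_equal()] false).  These are the
#' pairs a curator reviews to reconcile the definitions (e.g. an
#' anatomical filler chosen differently on the two sides) or demote the
#' mapping.
#'
#' @param manual a [mapping_set()] of curated mappings.
#' @param mp,hp the two ontologies.
#' @return a `discrepancy_report` whose `items` data frame has columns
#'   `subject_id`, `object_id`, `detail`.
#' @export
report_exact_without_logical_agreement <- function(manual, mp, hp) {
  stopifnot(inherits(manual, "mapping_set"))
  m <- manual$mappings
  m <- m[m$predicate_id == "skos:exactMatch", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(m))) {
    s <- m$subject_id[i]; o <- m$object_id[i]
    ts <- mp$terms[[s]]; to <- hp$terms[[o]]
    detail <- if (is.null(ts) || is.null(to)) {
      "term not found in ontology"
    } else if (is.null(ts$logical_def) || is.null(to$logical_def)) {
      "logical definition absent"
    } else if (!eq_equal(ts$logical_def, to$logical_def)) {
      "logical definitions differ"
    } else {
      NA_character_
    }
    if (!is.na(detail)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s, object_id = o, detail = detail,
        stringsAsFactors = FALSE)
    }
  }
  items <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), object_id = character(),
               detail = character(), stringsAsFactors = FALSE)
  items <- items[order(items$subject_id, items$object_id), , drop = FALSE]
  rownames(items) <- NULL
  discrepancy_report("exact_without_logical_agreement", items)
}

#' Report identical logical definitions not manually mapped as exact
#'
#' The converse check: every (MP, HP) pair with identical logical
#' definitions whose manual mapping is missing or carries a predicate
#' other than `skos:exactMatch` (e.g. a narrowMatch kept because the text
#' definition carries nuance the logical definition lacks).
#'
#' @inheritParams report_exact_without_logical_agreement
#' @return a `discrepancy_report` with columns `subject_id`, `object_id`,
#'   `detail`.
#' @export
report_logical_without_exact_mapping <- function(manual, mp, hp) {
  stopifnot(inherits(manual, "mapping_set"))
  lm <- logical_match(mp, hp)$mappings
  man <- manual$mappings
  man_key <- paste(man$subject_id, man$object_id, sep = "\r")
  rows <- list()
  for (i in seq_len(nrow(lm))) {
    k <- paste(lm$subject_id[i], lm$object_id[i], sep = "\r")
    hit <- which(man_key == k)
    detail <- if (!length(hit)) {
      "pair not manually mapped"
    } else if (any(man$predicate_id[hit] == "skos:exactMatch")) {
      NA_character_
    } else {
      paste0("manual mapping is ",
             paste(unique(man$predicate_id[hit]), collapse = ", "))
    }
    if (!is.na(detail)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = lm$subject_id[i], object_id = lm$object_id[i],
        detail = detail, stringsAsFactors = FALSE)
    }
  }
  items <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), object_id = character(),
               detail = character(), stringsAsFactors = FALSE)
  rownames(items) <- NULL
  discrepancy_report("logical_without_exact_mapping", items)
}

#' Report terms with multiple exact lexical matches
#'
#' Lists every subject participating in two or more `skos:exactMatch`
#' lexical rows, and symmetrically every such object.  Multiple exact
#' matches usually indicate a synonym whose scope should be revisited
#' (e.g. an "osteopenia" synonym that is really narrower than its term).
#'
#' @param lexical a [mapping_set()] produced by [lexical_match()].
#' @return a `discrepancy_report` with columns `id`, `side`
#'   (`"subject"`/`"object"`), `partners` (pipe-delimited ids).
#' @export
report_multi_exact_lexical <- function(lexical) {
  stopifnot(inherits(lexical, "mapping_set"))
  lx <- lexical$mappings
  lx <- lx[lx$predicate_id == "skos:exactMatch" & lx$method == "lexical", ,
           drop = FALSE]
  collect <- function(ids, partners, side) {
    tab <- table(ids)
    hot <- names(tab)[tab >= 2L]
    if (!length(hot)) {
      return(data.frame(id = character(), side = character(),
                        partners = character(), stringsAsFactors = FALSE))
    }
    data.frame(
      id = hot, side = side,
      partners = vapply(hot, function(h)
        paste(sort(partners[ids == h]), collapse = "|"), ""),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  items <- rbind(collect(lx$subject_id, lx$object_id, "subject"),
                 collect(lx$object_id, lx$subject_id, "object"))
  items <- items[order(items$side, items$id), , drop = FALSE]
  rownames(items) <- NULL
  discrepancy_report("multi_exact_lexical", items)
}

#' Write a discrepancy report as TSV
#'
#' @param report a `discrepancy_report` (or list of them, concatenated
#'   with a `kind` column).
#' @param path output file path.
#' @param header_lines optional `#`-prefixed comment lines.
#' @return the written data frame, invisibly.
#' @export
write_report_tsv <- function(report, path, header_lines = character()) {
  reports <- if (inherits(report, "discrepancy_report")) list(report) else report
  dfs <- lapply(reports, function(r) {
    if (!nrow(r$items)) {
      return(NULL)
    }
    cbind(data.frame(kind = r$kind, stringsAsFactors = FALSE), r$items)
  })
  dfs <- dfs[!vapply(dfs, is.null, TRUE)]
  cols <- unique(unlist(lapply(reports, function(r) c("kind", names(r$items)))))
  if (length(dfs)) {
    dfs <- lapply(dfs, function(d) {
      for (cn in setdiff(cols, names(d))) d[[cn]] <- ""
      d[, cols, drop = FALSE]
    })
    df <- do.call(rbind, dfs)
  } else {
    df <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                        stringsAsFactors = FALSE)
  }
  lines <- c(header_lines, paste(cols, collapse = "\t"))
  if (nrow(df)) lines <- c(lines, do.call(paste, c(df, sep = "\t")))
  writeLines(lines, path)
  invisible(df)
}
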