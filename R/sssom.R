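# SSSOM TSV mapping-set I/O, plus the free-text sign/symptom dialect.

#' SKOS mapping predicates
#'
#' The five mapping predicates used throughout the package.  Mappings are
#' oriented MP-side subject to HP-side object, so `skos:narrowMatch` means
#' the object (human) term covers a narrower concept than the subject.
#'
#' @return character vector of predicate CURIEs.
#' @export
skos_predicates <- function() {
  c("skos:exactMatch", "skos:narrowMatch", "skos:broadMatch",
    "skos:relatedMatch", "skos:closeMatch")
}

sssom_columns <- function() {
  c("subject_id", "subject_label", "predicate_id", "object_id",
    "object_label", "method", "author_id", "mapping_date", "comment")
}

method_justification <- c(
  manual  = "semapv:ManualMappingCuration",
  logical = "semapv:LogicalReasoning",
  lexical = "semapv:LexicalMatching"
)

#' An empty mappings data frame
#'
#' @return zero-row data frame with the standard mapping columns.
#' @export
empty_mappings <- function() {
  cols <- sssom_columns()
  out <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                       stringsAsFactors = FALSE)
  out
}

#' Construct a mapping set
#'
#' A mapping set is a data frame of subject(MP)->object(HP) assertions plus
#' header metadata.  Each row carries a SKOS predicate, the producing
#' method (`manual`, `logical` or `lexical`), curator ORCIDs
#' (pipe-delimited when several), a date and a free-text comment.  Exact
#' duplicate `(subject, object, predicate, method)` rows are collapsed.
#'
#' @param mappings data frame with at least the columns of
#'   [empty_mappings()]; extra columns are preserved.
#' @param metadata named list of header metadata (license,
#'   mapping_set_id, ...), values coerced to strings.
#' @param subject_prefix,object_prefix when non-`NULL`, every subject
#'   (resp. object) id must use this prefix; pass `NULL` to allow other
#'   ontology pairs.
#' @return an object of class `mapping_set`.
#' @export
mapping_set <- function(mappings = empty_mappings(), metadata = list(),
                        subject_prefix = NULL, object_prefix = NULL) {
  stopifnot(is.data.frame(mappings))
  need <- setdiff(sssom_columns(), names(mappings))
  for (cn in need) mappings[[cn]] <- rep("", nrow(mappings))
  mappings <- mappings[, c(sssom_columns(),
                           setdiff(names(mappings), sssom_columns())),
                       drop = FALSE]
  bad_pred <- setdiff(unique(mappings$predicate_id), skos_predicates())
  if (length(bad_pred)) {
    stop("invalid predicate_id: ", paste(bad_pred, collapse = ", "))
  }
  bad_method <- setdiff(unique(mappings$method), names(method_justification))
  if (length(bad_method)) {
    stop("invalid method: ", paste(bad_method, collapse = ", "))
  }
  if (!is.null(subject_prefix)) {
    ok <- startsWith(mappings$subject_id, paste0(subject_prefix, ":"))
    if (!all(ok)) stop("subject_id outside prefix ", subject_prefix, ": ",
                       paste(mappings$subject_id[!ok], collapse = ", "))
  }
  if (!is.null(object_prefix)) {
    ok <- startsWith(mappings$object_id, paste0(object_prefix, ":"))
    if (!all(ok)) stop("object_id outside prefix ", object_prefix, ": ",
                       paste(mappings$object_id[!ok], collapse = ", "))
  }
  key <- paste(mappings$subject_id, mappings$object_id,
               mappings$predicate_id, mappings$method, sep = "\r")
  mappings <- mappings[!duplicated(key), , drop = FALSE]
  rownames(mappings) <- NULL
  structure(list(mappings = mappings,
                 metadata = lapply(metadata, as.character)),
            class = "mapping_set")
}

#' @export
print.mapping_set <- function(x, ...) {
  cat("<mapping_set> ", nrow(x$mappings), " mappings\n", sep = "")
  if (nrow(x$mappings)) {
    tab <- table(x$mappings$method, x$mappings$predicate_id)
    print(tab)
  }
  invisible(x)
}

#' Write a mapping set as SSSOM TSV
#'
#' Emits `#`-prefixed metadata header lines, a column header and one row
#' per mapping, sorted by `(subject_id, object_id, predicate_id)` so the
#' same set always produces a byte-identical file.  The stored `method`
#' enum is serialized as a `mapping_justification` token
#' (`semapv:ManualMappingCuration`, `semapv:LogicalReasoning`,
#' `semapv:LexicalMatching`).  Extra columns are written after the
#' standard ones.
#'
#' @param set a [mapping_set()].
#' @param path optional output path.
#' @return the document as a single string, invisibly when `path` given.
#' @export
write_sssom <- function(set, path = NULL) {
  stopifnot(inherits(set, "mapping_set"))
  md <- set$metadata
  md_lines <- if (length(md)) {
    keys <- sort(names(md))
    paste0("#", keys, ": ", vapply(md[keys], paste, "", collapse = "|"))
  } else character()

  df <- set$mappings
  df$mapping_justification <- unname(method_justification[df$method])
  extras <- setdiff(names(df), c(sssom_columns(), "mapping_justification"))
  cols <- c("subject_id", "subject_label", "predicate_id", "object_id",
            "object_label", "mapping_justification", "author_id",
            "mapping_date", "comment", extras)
  ord <- order(df$subject_id, df$object_id, df$predicate_id,
               df$mapping_justification)
  df <- df[ord, cols, drop = FALSE]
  lines <- c(md_lines, paste(cols, collapse = "\t"))
  if (nrow(df)) lines <- c(lines, do.call(paste, c(df, sep = "\t")))
  doc <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(doc))
  }
  doc
}

split_tsv_row <- function(line, n) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  length(parts) <- n          # pad with NA
  parts[is.na(parts)] <- ""
  parts
}

#' Read a mapping set from SSSOM TSV
#'
#' Parses the `#key: value` metadata header, validates required columns
#' and predicate values (strict case: `skos:exactMatch`, not
#' `skos:exactmatch`), maps `mapping_justification` back to the method
#' enum and preserves unknown extra columns for round-tripping.
#'
#' @param text document text (string or lines) or a file path.
#' @return a [mapping_set()].
#' @export
read_sssom <- function(text) {
  lines <- sssom_input_lines(text)
  meta_lines <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  metadata <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#([A-Za-z0-9_]+): ?(.*)$", ml))[[1L]]
    if (length(m) == 3L) metadata[[m[2L]]] <- m[3L]
  }
  if (!length(body)) stop("no column header row found")
  cols <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  required <- c("subject_id", "subject_label", "predicate_id", "object_id",
                "object_label", "mapping_justification")
  miss <- setdiff(required, cols)
  if (length(miss)) stop("missing required column: ", paste(miss, collapse = ", "))

  rows <- body[-1L]
  cells <- lapply(rows, split_tsv_row, n = length(cols))
  df <- as.data.frame(do.call(rbind, c(cells, list(deparse.level = 0))),
                      stringsAsFactors = FALSE)
  if (!length(rows)) {
    df <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                        stringsAsFactors = FALSE)
  } else {
    names(df) <- cols
  }

  bad <- which(!df$predicate_id %in% skos_predicates())
  if (length(bad)) {
    stop("row ", bad[1L], ": invalid predicate_id '", df$predicate_id[bad[1L]], "'")
  }
  rev_map <- setNames(names(method_justification), method_justification)
  badj <- which(!df$mapping_justification %in% names(rev_map))
  if (length(badj)) {
    stop("row ", badj[1L], ": unknown mapping_justification '",
         df$mapping_justification[badj[1L]], "'")
  }
  df$method <- unname(rev_map[df$mapping_justification])
  df$mapping_justification <- NULL
  for (cn in c("author_id", "mapping_date", "comment")) {
    if (is.null(df[[cn]])) df[[cn]] <- rep("", nrow(df))
  }
  mapping_set(df, metadata = metadata)
}

sssom_input_lines <- function(text) {
  stopifnot(is.character(text))
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  sub("\r$", "", lines)
}

#' Construct a sign/symptom mapping row
#'
#' The free-text dialect records a sign or symptom description from the
#' literature together with the MP and HP terms it maps to and its source
#' citations.  Either id list may be empty: not every sign or symptom has
#' a matching term in both ontologies (e.g. "brain fog" maps to an HP
#' term only).
#'
#' @param description free-text description (non-empty).
#' @param mp_ids,hp_ids character vectors of CURIEs (possibly empty).
#' @param source_refs character vector of citation strings.
#' @return an object of class `symptom_mapping`.
#' @export
symptom_mapping <- function(description, mp_ids = character(),
                            hp_ids = character(), source_refs = character()) {
  stopifnot(is.character(description), length(description) == 1L,
            nzchar(description))
  structure(list(description = description,
                 mp_ids = as.character(mp_ids),
                 hp_ids = as.character(hp_ids),
                 source_refs = as.character(source_refs)),
            class = "symptom_mapping")
}

#' Write a sign/symptom mapping table as TSV
#'
#' Columns: `description`, pipe-delimited `mp_ids` and `hp_ids`, and
#' pipe-delimited `source_refs`.
#'
#' @param rows list of [symptom_mapping()] objects.
#' @param path optional output path.
#' @param header_lines optional `#`-prefixed lines to prepend.
#' @return the document as a single string, invisibly when `path` given.
#' @export
write_symptom_table <- function(rows, path = NULL, header_lines = character()) {
  body <- vapply(rows, function(r) {
    paste(r$description,
          paste(r$mp_ids, collapse = "|"),
          paste(r$hp_ids, collapse = "|"),
          paste(r$source_refs, collapse = "|"),
          sep = "\t")
  }, character(1L))
  lines <- c(header_lines,
             "description\tmp_ids\thp_ids\tsource_refs", body)
  doc <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(doc))
  }
  doc
}

#' Read a sign/symptom mapping table
#'
#' @param text document text (string or lines) or a file path.
#' @return list of [symptom_mapping()] objects.
#' @export
read_symptom_table <- function(text) {
  lines <- sssom_input_lines(text)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(list())
  cols <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("description", "mp_ids", "hp_ids", "source_refs")
  miss <- setdiff(need, cols)
  if (length(miss)) stop("missing required column: ", paste(miss, collapse = ", "))
  pipe_split <- function(x) if (nzchar(x)) strsplit(x, "|", fixed = TRUE)[[1L]] else character()
  out <- vector("list", length(lines) - 1L)
  for (i in seq_along(out)) {
    parts <- split_tsv_row(lines[i + 1L], length(cols))
    names(parts) <- cols
    if (!nzchar(parts[["description"]])) stop("row ", i, ": empty description")
    out[[i]] <- symptom_mapping(parts[["description"]],
                                mp_ids = pipe_split(parts[["mp_ids"]]),
                                hp_ids = pipe_split(parts[["hp_ids"]]),
                                source_refs = pipe_split(parts[["source_refs"]]))
  }
  out
}
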