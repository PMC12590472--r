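# OBO-dialect reader and writer.
#
# Supported tags: id, name, def, synonym (EXACT/NARROW/BROAD/RELATED),
# is_a, intersection_of (genus line and relation+filler lines),
# is_obsolete, replaced_by, created_by/contributor, creation_date.
# Any other tag-value line inside a [Term] stanza is preserved opaquely
# and re-emitted on write; non-[Term] stanzas are preserved verbatim.
# Obsolete terms are written with the conventional "obsolete " label
# prefix, which the parser strips again, so parse(write(x)) == x.

#' Parse an OBO-dialect document into an ontology
#'
#' @param text the document: either a single string (with embedded
#'   newlines) or a character vector of lines.
#' @return a [ontology()] object.
#' @seealso [read_obo()] to read from a file, [write_obo()] for the
#'   inverse operation.
#' @export
parse_obo <- function(text) {
  stopifnot(is.character(text))
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  lines <- sub("\r$", "", lines)

  stanza_start <- grep("^\\[[A-Za-z-]+\\]$", lines)
  header_lines <- if (length(stanza_start)) lines[seq_len(stanza_start[1L] - 1L)] else lines

  prefix <- NA_character_
  header_extra <- character()
  for (hl in header_lines) {
    if (!nzchar(trimws(hl))) next
    m <- regmatches(hl, regexec("^([A-Za-z_-]+): ?(.*)$", hl))[[1L]]
    if (length(m) == 3L && m[2L] == "ontology") {
      prefix <- toupper(trimws(m[3L]))
    } else if (length(m) == 3L && m[2L] == "format-version") {
      # standard line, regenerated on write
    } else {
      header_extra <- c(header_extra, hl)
    }
  }
  if (is.na(prefix)) prefix <- "ONTO"

  terms <- list()
  extra_stanzas <- list()
  bounds <- c(stanza_start, length(lines) + 1L)
  ordinal <- 0L
  for (i in seq_along(stanza_start)) {
    head_line <- lines[stanza_start[i]]
    block <- lines[seq.int(stanza_start[i] + 1L, bounds[i + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    if (head_line != "[Term]") {
      extra_stanzas <- c(extra_stanzas, list(c(head_line, block)))
      next
    }
    ordinal <- ordinal + 1L
    term <- parse_term_stanza(block, ordinal)
    if (term$id %in% vapply(terms, function(t) t$id, "")) {
      stop("duplicate term id: ", term$id)
    }
    terms <- c(terms, list(term))
  }
  ontology(prefix, terms, header = header_extra, extra_stanzas = extra_stanzas)
}

#' Read an OBO-dialect file
#'
#' @param path path to the file.
#' @return a [ontology()] object.
#' @export
read_obo <- function(path) parse_obo(readLines(path, warn = FALSE))

# strip a trailing " ! label" comment from a CURIE-valued tag
strip_obo_comment <- function(v) trimws(sub("[ \t]+!.*$", "", v))

parse_quoted <- function(val) {
  m <- regmatches(val, regexec('^"((?:[^"\\\\]|\\\\.)*)"', val))[[1L]]
  if (!length(m)) return(NULL)
  list(text = gsub("\\\\(.)", "\\1", m[2L]),
       rest = trimws(substring(val, nchar(m[1L]) + 1L)))
}

parse_term_stanza <- function(block, ordinal) {
  id <- NULL; label <- NULL; definition <- NULL
  synonyms <- list(); parents <- character()
  genus <- NULL; mods <- list()
  deprecated <- FALSE; replaced_by <- NULL
  contributors <- character(); creation_date <- NULL
  other <- character()

  for (line in block) {
    if (startsWith(line, "!")) next
    m <- regmatches(line, regexec("^([A-Za-z_]+): ?(.*)$", line))[[1L]]
    if (!length(m)) { other <- c(other, line); next }
    tag <- m[2L]; val <- m[3L]
    if (tag == "id") {
      id <- strip_obo_comment(val)
    } else if (tag == "name") {
      label <- trimws(val)
    } else if (tag == "def") {
      q <- parse_quoted(val)
      if (is.null(q)) stop("stanza ", ordinal, ": malformed def line")
      definition <- q$text
    } else if (tag == "synonym") {
      q <- parse_quoted(val)
      if (is.null(q)) stop("stanza ", ordinal, ": malformed synonym line")
      sm <- regmatches(q$rest, regexec("^(EXACT|NARROW|BROAD|RELATED)\\b", q$rest))[[1L]]
      scope <- if (length(sm)) tolower(sm[2L]) else "related"
      synonyms <- c(synonyms, list(synonym(q$text, scope)))
    } else if (tag == "is_a") {
      parents <- c(parents, strip_obo_comment(val))
    } else if (tag == "intersection_of") {
      v <- strip_obo_comment(val)
      parts <- strsplit(v, "[ \t]+")[[1L]]
      if (length(parts) == 1L) {
        genus <- parts[1L]
      } else {
        mods <- c(mods, list(list(relation = parts[1L], filler = parts[2L])))
      }
    } else if (tag == "is_obsolete") {
      deprecated <- identical(trimws(val), "true")
    } else if (tag == "replaced_by") {
      replaced_by <- strip_obo_comment(val)
    } else if (tag %in% c("created_by", "contributor")) {
      contributors <- c(contributors, trimws(val))
    } else if (tag == "creation_date") {
      creation_date <- trimws(val)
    } else {
      other <- c(other, line)
    }
  }
  if (is.null(id)) stop("stanza ", ordinal, ": missing id")
  if (is.null(label)) label <- ""
  if (deprecated && startsWith(label, "obsolete ")) {
    label <- substring(label, nchar("obsolete ") + 1L)
  }
  logical_def <- NULL
  if (!is.null(genus) && !deprecated) {
    logical_def <- eq_expression(genus, mods, allowed_relations = NULL)
  }
  pheno_term(id = id, label = label, definition = definition,
             synonyms = synonyms, parents = parents,
             logical_def = logical_def, deprecated = deprecated,
             replaced_by = replaced_by, contributors = contributors,
             creation_date = creation_date, other = other)
}

obo_escape <- function(x) gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x))

term_stanza_lines <- function(t) {
  out <- c("[Term]",
           paste0("id: ", t$id),
           paste0("name: ", if (t$deprecated) paste0("obsolete ", t$label) else t$label))
  if (!is.null(t$definition)) {
    out <- c(out, paste0('def: "', obo_escape(t$definition), '" []'))
  }
  for (s in t$synonyms) {
    out <- c(out, paste0('synonym: "', obo_escape(s$text), '" ',
                         toupper(s$scope), " []"))
  }
  for (p in t$parents) out <- c(out, paste0("is_a: ", p))
  if (!is.null(t$logical_def)) {
    eq <- t$logical_def
    out <- c(out, paste0("intersection_of: ", eq$genus))
    if (nrow(eq$modifiers)) {
      out <- c(out, paste0("intersection_of: ", eq$modifiers$relation, " ",
                           eq$modifiers$filler))
    }
  }
  if (t$deprecated) out <- c(out, "is_obsolete: true")
  if (!is.null(t$replaced_by)) out <- c(out, paste0("replaced_by: ", t$replaced_by))
  for (cb in t$contributors) out <- c(out, paste0("contributor: ", cb))
  if (!is.null(t$creation_date)) out <- c(out, paste0("creation_date: ", t$creation_date))
  c(out, t$other)
}

#' Write an ontology as an OBO-dialect document
#'
#' The inverse of [parse_obo()] on the dialect subset:
#' `parse_obo(write_obo(onto))` reproduces `onto` field for field.
#' Deprecated terms get the conventional `"obsolete "` label prefix;
#' logical definitions are emitted in canonical modifier order; output is
#' deterministic for a given ontology object.
#'
#' @param onto a [ontology()] object.
#' @param path optional file path; when given the document is also written
#'   to disk.
#' @return the document as a single string, invisibly when `path` is given.
#' @export
write_obo <- function(onto, path = NULL) {
  stopifnot(inherits(onto, "pheno_ontology"))
  out <- c("format-version: 1.2",
           paste0("ontology: ", tolower(onto$prefix)),
           onto$header)
  chunks <- lapply(onto$terms, term_stanza_lines)
  for (ch in chunks) out <- c(out, "", ch)
  for (st in onto$extra_stanzas) out <- c(out, "", st)
  doc <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(doc))
  }
  doc
}
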