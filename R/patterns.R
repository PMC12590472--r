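# Pattern-driven logical-definition generation (uPheno-style templates).
#
# A pattern is a template EQ expression whose genus and modifier fillers
# are either constant CURIEs or variable names; each variable declares the
# ontology prefix its fillers must come from.  A filler table binds each
# target term id to one filler per variable; applying the pattern replaces
# the term's logical definition with the instantiated template.

#' Read a logical-definition pattern
#'
#' Patterns are stored as small YAML files, e.g.
#' ```
#' pattern_id: abnormalMorphologyOfPartOfAnatomicalEntity
#' variables:
#'   anatomical_entity: UBERON
#' template:
#'   genus: PATO:0000051
#'   modifiers:
#'     - relation: characteristic_of_part_of
#'       filler: anatomical_entity
#'     - relation: has_modifier
#'       filler: PATO:0000460
#' ```
#' A template filler that names a declared variable is substituted at
#' application time; anything else must be a constant CURIE.
#'
#' @param x a file path or the YAML text itself.
#' @return an object of class `upheno_pattern`.
#' @export
read_pattern <- function(x) {
  txt <- if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  p <- yaml::yaml.load(txt)
  stopifnot(is.character(p$pattern_id), nzchar(p$pattern_id),
            is.list(p$template))
  vars <- lapply(p$variables, as.character)
  if (is.null(vars)) vars <- list()
  fillers <- c(p$template$genus,
               vapply(p$template$modifiers, function(m) as.character(m$filler), ""))
  is_curie <- grepl(":", fillers, fixed = TRUE)
  undeclared <- setdiff(fillers[!is_curie], names(vars))
  if (length(undeclared)) {
    stop("template uses undeclared variable(s): ",
         paste(undeclared, collapse = ", "))
  }
  structure(list(pattern_id = p$pattern_id, variables = vars,
                 template = p$template), class = "upheno_pattern")
}

#' Read a filler table (one row per term)
#'
#' TSV with a `term_id` column plus one column per pattern variable.
#'
#' @param text document text (string or lines) or a file path.
#' @return data frame.
#' @export
read_filler_table <- function(text) {
  lines <- sssom_input_lines(text)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("empty filler table")
  cols <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!"term_id" %in% cols) stop("missing required column: term_id")
  cells <- lapply(lines[-1L], split_tsv_row, n = length(cols))
  if (!length(cells)) {
    df <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                        stringsAsFactors = FALSE)
    return(df)
  }
  df <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

#' Validate a filler table against a pattern
#'
#' Every row must bind every declared variable with a CURIE whose prefix
#' matches the variable's allowed ontology, and carry a non-empty
#' `term_id`.
#'
#' @param pattern a [read_pattern()] object.
#' @param table a filler-table data frame.
#' @return data frame of violations with columns `row`, `variable`,
#'   `problem`; zero rows when the table is valid.
#' @export
validate_filler_table <- function(pattern, table) {
  stopifnot(inherits(pattern, "upheno_pattern"), is.data.frame(table))
  viol <- list()
  add <- function(row, variable, problem) {
    viol[[length(viol) + 1L]] <<- data.frame(
      row = row, variable = variable, problem = problem,
      stringsAsFactors = FALSE)
  }
  n <- nrow(table)
  tid <- if ("term_id" %in% names(table)) as.character(table$term_id) else rep("", n)
  for (i in seq_len(n)) {
    if (!nzchar(tid[i]) || is.na(tid[i])) add(i, "term_id", "missing binding")
  }
  for (v in names(pattern$variables)) {
    allowed <- pattern$variables[[v]]
    col <- if (v %in% names(table)) as.character(table[[v]]) else rep(NA_character_, n)
    for (i in seq_len(n)) {
      val <- col[i]
      if (is.na(val) || !nzchar(val)) {
        add(i, v, "missing binding")
      } else {
        pfx <- sub(":.*$", "", val)
        if (!identical(pfx, allowed)) {
          add(i, v, paste0("prefix ", allowed, " required, got ", pfx))
        }
      }
    }
  }
  if (!length(viol)) {
    return(data.frame(row = integer(), variable = character(),
                      problem = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, viol)
  out <- out[order(out$row, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  out
}

instantiate_pattern <- function(pattern, bindings) {
  resolve <- function(x) {
    if (x %in% names(pattern$variables)) bindings[[x]] else x
  }
  genus <- resolve(pattern$template$genus)
  mods <- lapply(pattern$template$modifiers, function(m) {
    list(relation = as.character(m$relation), filler = resolve(as.character(m$filler)))
  })
  canonicalize_eq(eq_expression(genus, mods, allowed_relations = NULL))
}

#' Apply a pattern to an ontology via a filler table
#'
#' For each table row, the target term's logical definition is replaced by
#' the instantiated template (any pre-existing logical definition is
#' discarded).  All other term fields are untouched, terms not in the
#' table are untouched, and re-applying the same table is a no-op.
#'
#' @param pattern a [read_pattern()] object.
#' @param table a filler-table data frame (see [read_filler_table()]).
#' @param onto the ontology to update.
#' @return the updated ontology.
#' @export
apply_pattern <- function(pattern, table, onto) {
  stopifnot(inherits(onto, "pheno_ontology"))
  v <- validate_filler_table(pattern, table)
  if (nrow(v)) {
    stop("invalid filler table: row ", v$row[1L], ", variable '",
         v$variable[1L], "': ", v$problem[1L])
  }
  ids <- as.character(table$term_id)
  unknown <- setdiff(ids, names(onto$terms))
  if (length(unknown)) stop("unknown term_id: ", paste(unknown, collapse = ", "))
  for (i in seq_along(ids)) {
    bindings <- lapply(names(pattern$variables),
                       function(v) as.character(table[[v]][i]))
    names(bindings) <- names(pattern$variables)
    onto$terms[[ids[i]]]$logical_def <- instantiate_pattern(pattern, bindings)
  }
  onto
}
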