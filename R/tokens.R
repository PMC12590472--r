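#' Normalize a label into a token bag
#'
#' Lowercases the string, replaces punctuation (`,;:.()/'-`) with spaces,
#' splits on whitespace, drops empty tokens and returns the sorted multiset
#' of tokens.  Token-bag equality is the match criterion used by
#' [lexical_match()]: two strings match when all their words agree,
#' irrespective of order, case and punctuation.  Multiplicity is preserved,
#' so "cleft lip, cleft palate" contains the token "cleft" twice.
#'
#' @param text a length-one character vector (may be empty).
#' @return a sorted character vector of tokens; `character(0)` for an
#'   empty or all-punctuation input.
#' @examples
#' normalize_label("Cleft lip, cleft palate")
#' identical(
#'   normalize_label("decreased bone mineral density"),
#'   normalize_label("Decreased Bone-Mineral Density")
#' )
#' @export
normalize_label <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  x <- tolower(text)
  x <- gsub("[,;:.()/'-]", " ", x)
  tokens <- strsplit(x, "[[:space:]]+")[[1L]]
  sort(tokens[nzchar(tokens)])
}

# canonical string key for a token bag
bag_key <- function(tokens) paste(tokens, collapse = " ")

label_key <- function(text) bag_key(normalize_label(text))

label_keys <- function(texts) {
  vapply(texts, label_key, character(1L), USE.NAMES = FALSE)
}
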