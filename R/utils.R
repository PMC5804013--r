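#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

#' Normalize a keyword or entity surface form
#'
#' Lowercases and collapses internal whitespace runs to a single space,
#' trimming the ends. All dictionary keywords, entity names and free text are
#' pushed through the same normalization so matching is deterministic across
#' title, abstract and MeSH-term fields.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_keyword("  Lung   Neoplasms ")
normalize_keyword <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Tokenize normalized text into lowercase alphanumeric tokens. Everything that
# is not [a-z0-9] is a separator, so "E. coli" -> c("e", "coli").
tokenize <- function(text) {
  text <- normalize_keyword(text)
  if (!nzchar(text)) {
    return(character(0))
  }
  toks <- strsplit(text, "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# Condition helper for CLI usage errors (exit code 2) vs data errors (exit 1).
usage_error <- function(message) {
  abort(message, class = "litgda_usage_error")
}

# Write a small JSON manifest next to an output, recording enough to re-run.
write_manifest <- function(path, fields) {
  jsonlite::write_json(fields, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower) {
    abort(sprintf("`%s` must be a single number >= %s", name, lower))
  }
  invisible(TRUE)
}
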