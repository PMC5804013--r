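#' Sum each keyword's weighted values across document vectors
#'
#' The inverse-frequency factor is driven by how much total (normalized)
#' weight a keyword accumulates across the document vectors in scope, not by
#' a document count.
#'
#' @param doc_vectors A tibble with at least columns `keyword`, `weight`
#'   (e.g. from [vectorize_corpus()], possibly filtered to one scope).
#' @return A tibble with columns `keyword`, `sum_w`; keys are exactly the
#'   union of vector supports.
#' @export
corpus_sums <- function(doc_vectors) {
  if (nrow(doc_vectors) == 0L) {
    return(tibble(keyword = character(0), sum_w = numeric(0)))
  }
  doc_vectors %>%
    dplyr::group_by(.data$keyword) %>%
    dplyr::summarise(sum_w = sum(.data$weight), .groups = "drop") %>%
    dplyr::arrange(.data$keyword)
}

#' Inverse document frequency of a keyword
#'
#' \deqn{IDF = \sqrt{1 / \sum w}}
#' The more total weight a keyword accumulates across document vectors, the
#' smaller its IDF.
#'
#' @param sum_w Positive numeric vector of summed weighted values.
#' @return Numeric vector of IDF values.
#' @export
#' @examples
#' idf(c(0.25, 1, 4)) # 2 1 0.5
idf <- function(sum_w) {
  if (length(sum_w) == 0L) {
    return(numeric(0))
  }
  if (any(!is.finite(sum_w)) || any(sum_w <= 0)) {
    abort("`sum_w` must be > 0 (IDF is undefined at zero total weight)")
  }
  sqrt(1 / sum_w)
}

#' Final term weights: TW = IDF x PWK
#'
#' Multiplies each keyword's inverse-frequency factor by the depth penalty
#' from its position(s) in the MeSH tree. With `use_pwk = FALSE` the penalty
#' factor is 1 everywhere, which reproduces the no-penalty ablation.
#'
#' @param stats A tibble from [corpus_sums()].
#' @param dict A `mesh_dict` tibble covering every keyword in `stats`.
#' @param use_pwk Apply the depth penalty? Default `TRUE`.
#' @param depth_rule Multi-position depth aggregation, `"max"` or `"min"`
#'   (see [keyword_depth()]).
#' @return A tibble with columns `keyword`, `sum_w`, `depth`, `idf`, `pwk`,
#'   `tw`.
#' @export
term_weights <- function(stats, dict, use_pwk = TRUE,
                         depth_rule = c("max", "min")) {
  depth_rule <- match.arg(depth_rule)
  if (nrow(stats) == 0L) {
    return(tibble(keyword = character(0), sum_w = numeric(0),
                  depth = integer(0), idf = numeric(0), pwk = numeric(0),
                  tw = numeric(0)))
  }
  depths <- keyword_depth(dict, depth_rule)
  missing <- setdiff(stats$keyword, depths$keyword)
  if (length(missing) > 0L) {
    abort(sprintf("keyword(s) in corpus stats missing from dictionary: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  stats %>%
    dplyr::left_join(depths, by = "keyword") %>%
    dplyr::mutate(idf = idf(.data$sum_w),
                  pwk = if (use_pwk) pwk(.data$depth) else 1,
                  tw = .data$idf * .data$pwk) %>%
    dplyr::arrange(.data$keyword)
}

#' Write term weights as a TSV for inspection or caching
#'
#' Columns: `keyword`, `sum_w`, `idf`, `pwk`, `tw`.
#'
#' @param tw A tibble from [term_weights()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_term_weights <- function(tw, path) {
  readr::write_tsv(dplyr::select(tw, "keyword", "sum_w", "idf", "pwk", "tw"),
                   path)
  invisible(path)
}
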