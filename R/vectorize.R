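#' Location weights for combining document vectors
#'
#' One document yields three kinds of location vectors: title keyword counts,
#' per-sentence keyword counts, and a binary indexed-MeSH-term vector. They
#' are combined into one representative vector with a scalar weight per
#' location. Indexed MeSH terms get the largest weight (they are curated
#' annotations), the title the next, and abstract sentences the least — with
#' a sentence upgraded to the title weight when it co-mentions the target
#' gene or disease.
#'
#' @param w_mesh Weight of the MeSH-term vector (default 3).
#' @param w_title Weight of the title vector (default 2).
#' @param w_abs_with Weight of an abstract sentence that co-mentions the
#'   target entity (default 2).
#' @param w_abs_without Weight of any other abstract sentence (default 1).
#' @return A list of class `weight_config`.
#' @export
weight_config <- function(w_mesh = 3, w_title = 2, w_abs_with = 2,
                          w_abs_without = 1) {
  w <- c(w_mesh = w_mesh, w_title = w_title, w_abs_with = w_abs_with,
         w_abs_without = w_abs_without)
  if (any(!is.finite(w)) || any(w < 0)) {
    abort("all location weights must be finite and >= 0")
  }
  if (all(w == 0)) {
    abort("at least one location weight must be > 0")
  }
  structure(as.list(w), class = "weight_config")
}

#' Uniform location weights (weight-matrix ablation)
#'
#' All four location weights set to 1, i.e. location information is ignored
#' when combining the three vectors.
#'
#' @return A `weight_config`.
#' @export
uniform_weights <- function() {
  weight_config(1, 1, 1, 1)
}

# Location vectors for one document, using a prebuilt phrase index.
# title: named counts; sentences: list of named counts; mesh: named 1s for
# keywords occurring among the indexed terms (binary by construction).
loc_vectors_internal <- function(title, sentences, mesh_terms, idx) {
  mesh_hits <- unlist(purrr::map(mesh_terms,
                                 ~ names(match_tokens(tokenize(.x), idx))))
  mesh_v <- if (length(mesh_hits) > 0L) {
    stats::setNames(rep(1L, length(unique(mesh_hits))), unique(mesh_hits))
  } else {
    stats::setNames(integer(0), character(0))
  }
  list(title = match_tokens(tokenize(title), idx),
       sentences = purrr::map(sentences, ~ match_tokens(tokenize(.x), idx)),
       mesh = mesh_v)
}

#' Build the three location vectors for one document
#'
#' @param title Document title.
#' @param sentences Character vector of abstract sentences (may be empty).
#' @param mesh_terms Character vector of indexed MeSH terms.
#' @param dict A `mesh_dict` tibble or character vector of keywords.
#' @return A list of class `location_vectors` with elements `title` (named
#'   keyword counts), `sentences` (list of named counts, one per sentence)
#'   and `mesh` (named binary vector: 1 if the keyword occurs among the
#'   indexed terms).
#' @export
build_location_vectors <- function(title, sentences, mesh_terms, dict) {
  kws <- if (is.data.frame(dict)) unique(dict$keyword) else dict
  lv <- loc_vectors_internal(title, sentences, mesh_terms, phrase_index(kws))
  structure(lv, class = "location_vectors")
}

# Weighted sum of named sparse vectors -> named numeric.
combine_internal <- function(lv, weights, entity_sentences) {
  s_w <- purrr::map_dbl(seq_along(lv$sentences), function(i) {
    if (i %in% entity_sentences) weights$w_abs_with else weights$w_abs_without
  })
  nm <- c(names(lv$title), names(lv$mesh),
          unlist(purrr::map(lv$sentences, names)))
  val <- c(weights$w_title * as.numeric(lv$title),
           weights$w_mesh * as.numeric(lv$mesh),
           unlist(purrr::map2(lv$sentences, s_w,
                              ~ .y * as.numeric(.x))))
  if (length(nm) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  out <- tapply(val, nm, sum)
  out <- stats::setNames(as.numeric(out), names(out))
  out[out > 0]
}

#' Combine location vectors into one raw representative vector
#'
#' `raw[k] = w_title * title[k] + sum_i s_i * sentence_i[k] +
#' w_mesh * mesh[k]`, where `s_i` is `w_abs_with` if sentence `i` co-mentions
#' the target entity and `w_abs_without` otherwise. The result is
#' entity-specific because of the sentence upgrade.
#'
#' @param locvecs A `location_vectors` object.
#' @param weights A [weight_config()].
#' @param entity_sentences Integer vector of 1-based sentence indices that
#'   mention the target entity.
#' @return A tibble with columns `keyword`, `weight` (raw, unnormalized).
#' @export
combine_locations <- function(locvecs, weights = weight_config(),
                              entity_sentences = integer(0)) {
  raw <- combine_internal(locvecs, weights, entity_sentences)
  tibble(keyword = names(raw), weight = unname(raw)) %>%
    dplyr::arrange(.data$keyword)
}

normalize_internal <- function(raw, method) {
  if (length(raw) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  if (any(raw < 0)) {
    abort("raw vector entries must be non-negative")
  }
  v <- switch(method, sum1 = raw, log = log1p(raw),
              abort(sprintf("unknown normalization method '%s'", method)))
  tot <- sum(v)
  if (tot == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  v / tot
}

#' Normalize a raw document vector
#'
#' `sum1` scales entries so they sum to 1, removing article-length bias.
#' `log` (the default elsewhere in the pipeline) first applies `log(1 + v)`
#' to damp large counts, then scales the transformed entries to sum to 1.
#'
#' @param raw A tibble with columns `keyword`, `weight`, or a named numeric
#'   vector.
#' @param method `"log"` or `"sum1"`.
#' @return A tibble with columns `keyword`, `weight`; non-empty results sum
#'   to 1.
#' @export
normalize_vector <- function(raw, method = c("log", "sum1")) {
  method <- match.arg(method)
  v <- if (is.data.frame(raw)) {
    stats::setNames(as.numeric(raw$weight), raw$keyword)
  } else {
    raw
  }
  out <- normalize_internal(v, method)
  tibble(keyword = names(out), weight = unname(out)) %>%
    dplyr::arrange(.data$keyword)
}

#' Vectorize every (entity, document) pair in a corpus
#'
#' For each entity and each document mentioning it, builds the three location
#' vectors, combines them with the entity-specific sentence weights, and
#' normalizes. Documents where the combined vector is empty (no dictionary
#' keyword in any field) contribute no rows.
#'
#' @param corpus A `lit_corpus` from [build_corpus()].
#' @param dict A `mesh_dict` tibble.
#' @param weights A [weight_config()].
#' @param norm_method `"log"` or `"sum1"`.
#' @return A tibble with columns `entity_id`, `kind`, `doc_id`, `keyword`,
#'   `weight`; within each (entity, document) the weights sum to 1.
#' @export
vectorize_corpus <- function(corpus, dict, weights = weight_config(),
                             norm_method = c("log", "sum1")) {
  norm_method <- match.arg(norm_method)
  docs <- corpus$documents
  if (nrow(docs) == 0L) {
    return(tibble(entity_id = character(0), kind = character(0),
                  doc_id = character(0), keyword = character(0),
                  weight = numeric(0)))
  }
  idx <- phrase_index(unique(dict$keyword))
  loc <- purrr::pmap(list(docs$title, docs$sentences, docs$mesh),
                     loc_vectors_internal, idx = idx)
  names(loc) <- docs$doc_id
  sm <- corpus$mentions %>% dplyr::filter(.data$field == "sentence")
  sent_key <- split(sm$sentence, paste(sm$doc_id, sm$entity_id, sep = "\r"))
  rows <- purrr::pmap(corpus$index, function(entity_id, kind, doc_id) {
    es <- sent_key[[paste(doc_id, entity_id, sep = "\r")]] %||% integer(0)
    raw <- combine_internal(loc[[doc_id]], weights, es)
    v <- normalize_internal(raw, norm_method)
    if (length(v) == 0L) {
      return(NULL)
    }
    tibble(entity_id = entity_id, kind = kind, doc_id = doc_id,
           keyword = names(v), weight = unname(v))
  })
  dplyr::bind_rows(rows) %>%
    dplyr::arrange(.data$entity_id, .data$doc_id, .data$keyword)
}
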