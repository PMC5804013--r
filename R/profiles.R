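#' Aggregate one entity's document vectors into a term-weighted profile
#'
#' The profile entry for keyword `k` is the sum of `k`'s weights over the
#' entity's document vectors, multiplied by the keyword's term weight.
#' Keywords with no term weight in scope (never observed in that scope's
#' corpus) contribute nothing.
#'
#' @param doc_vectors A tibble with columns `doc_id`, `keyword`, `weight` —
#'   the document vectors built for this entity.
#' @param tw A term-weight tibble from [term_weights()].
#' @return A tibble with columns `keyword`, `weight`; attribute `n_docs`
#'   carries the number of contributing documents.
#' @export
build_profile <- function(doc_vectors, tw) {
  n_docs <- length(unique(doc_vectors$doc_id))
  out <- doc_vectors %>%
    dplyr::group_by(.data$keyword) %>%
    dplyr::summarise(total = sum(.data$weight), .groups = "drop") %>%
    dplyr::inner_join(dplyr::select(tw, "keyword", "tw"), by = "keyword") %>%
    dplyr::transmute(keyword = .data$keyword,
                     weight = .data$total * .data$tw) %>%
    dplyr::arrange(.data$keyword)
  attr(out, "n_docs") <- n_docs
  out
}

#' Build every gene and disease profile
#'
#' One profile per lexicon entity, including empty profiles for entities
#' never mentioned in the corpus (their rows are absent from `profiles` but
#' present in `meta` with `n_docs = 0`), so the downstream association table
#' covers the full lexicon cross-product.
#'
#' @param doc_vectors Output of [vectorize_corpus()].
#' @param tw_gene,tw_disease Term weights for the gene and disease scopes
#'   ([term_weights()]); pass the same object twice for a joint scope.
#' @param gene_ids,disease_ids Character vectors of all lexicon entity ids.
#' @return A list of class `entity_profiles`: `profiles` (tibble:
#'   `entity_id`, `kind`, `keyword`, `weight`) and `meta` (tibble:
#'   `entity_id`, `kind`, `n_docs`), both ordered by `entity_id`.
#' @export
build_all_profiles <- function(doc_vectors, tw_gene, tw_disease,
                               gene_ids, disease_ids) {
  one_scope <- function(kind, ids, tw) {
    kind_val <- kind
    dv <- doc_vectors %>% dplyr::filter(.data$kind == kind_val)
    counts <- dv %>%
      dplyr::distinct(.data$entity_id, .data$doc_id) %>%
      dplyr::count(.data$entity_id, name = "n_docs")
    prof <- dv %>%
      dplyr::group_by(.data$entity_id, .data$keyword) %>%
      dplyr::summarise(total = sum(.data$weight), .groups = "drop") %>%
      dplyr::inner_join(dplyr::select(tw, "keyword", "tw"), by = "keyword") %>%
      dplyr::transmute(entity_id = .data$entity_id, kind = kind,
                       keyword = .data$keyword,
                       weight = .data$total * .data$tw)
    meta <- tibble(entity_id = sort(unique(ids)), kind = kind) %>%
      dplyr::left_join(counts, by = "entity_id") %>%
      dplyr::mutate(n_docs = dplyr::coalesce(.data$n_docs, 0L))
    list(prof = prof, meta = meta)
  }
  g <- one_scope("gene", gene_ids, tw_gene)
  d <- one_scope("disease", disease_ids, tw_disease)
  out <- list(
    profiles = dplyr::bind_rows(g$prof, d$prof) %>%
      dplyr::arrange(.data$kind, .data$entity_id, .data$keyword),
    meta = dplyr::bind_rows(g$meta, d$meta) %>%
      dplyr::arrange(.data$kind, .data$entity_id))
  class(out) <- "entity_profiles"
  out
}

#' @export
print.entity_profiles <- function(x, ...) {
  n <- table(x$meta$kind)
  cat(sprintf("<entity_profiles> %d genes, %d diseases, %d non-zero entries\n",
              n[["gene"]] %||% 0L, n[["disease"]] %||% 0L, nrow(x$profiles)))
  invisible(x)
}

#' Write profiles as sparse triplets with a manifest sidecar
#'
#' TSV columns `entity_id<TAB>keyword<TAB>weight`; the sidecar
#' (`<path>.manifest.json`) records entity/keyword counts and the options
#' passed in `info`.
#'
#' @param profiles An `entity_profiles` object.
#' @param path Output TSV path.
#' @param info Named list folded into the manifest.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, info = list()) {
  readr::write_tsv(
    dplyr::select(profiles$profiles, "entity_id", "keyword", "weight"), path)
  write_manifest(paste0(path, ".manifest.json"), c(list(
    n_entities = nrow(profiles$meta),
    n_keywords = length(unique(profiles$profiles$keyword))), info))
  invisible(path)
}
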