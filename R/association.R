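#' Cosine similarity between two sparse non-negative vectors
#'
#' \deqn{\cos(u, v) = \frac{u \cdot v}{|u||v|}}
#' Profiles are non-negative by construction, so the score lies in [0, 1].
#' If either vector is empty or all-zero the pair is degenerate and scores 0.
#'
#' @param v1,v2 Tibbles with columns `keyword`, `weight`, or named numeric
#'   vectors.
#' @return A single number in [0, 1].
#' @export
#' @examples
#' cosine_similarity(c(a = 1, b = 2), c(a = 2, b = 1)) # 0.8
cosine_similarity <- function(v1, v2) {
  as_vec <- function(v) {
    if (is.data.frame(v)) stats::setNames(as.numeric(v$weight), v$keyword) else v
  }
  u <- as_vec(v1)
  v <- as_vec(v2)
  if (any(u < 0) || any(v < 0)) {
    abort("cosine inputs must be non-negative (profiles are by construction)")
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    return(0)
  }
  shared <- intersect(names(u), names(v))
  if (length(shared) == 0L) {
    return(0)
  }
  sum(u[shared] * v[shared]) / (nu * nv)
}

# profiles triplets -> sparse keyword x entity matrix over a fixed keyword
# universe and entity order.
profile_matrix <- function(prof, kw_index, entity_order) {
  Matrix::sparseMatrix(
    i = kw_index[prof$keyword],
    j = match(prof$entity_id, entity_order),
    x = prof$weight,
    dims = c(length(kw_index), length(entity_order)))
}

#' Score every gene-disease pair by cosine similarity
#'
#' Computes the full lexicon cross-product. Pairs where either profile is
#' empty score 0 and are flagged `degenerate` rather than dropped, so
#' evaluation denominators stay well defined. Rows are ordered by `gene_id`,
#' then `disease_id`.
#'
#' @param profiles An `entity_profiles` object from [build_all_profiles()].
#' @param gold Optional gold-standard tibble with columns `gene_id`,
#'   `disease_id`; every referenced id must exist in one of the lexicons.
#' @return A tibble of class `gda_assoc` with columns `gene_id`,
#'   `disease_id`, `cosine`, `is_known`, `degenerate`.
#' @export
score_all <- function(profiles, gold = NULL) {
  meta <- profiles$meta
  genes <- meta$entity_id[meta$kind == "gene"]
  diseases <- meta$entity_id[meta$kind == "disease"]
  if (!is.null(gold) && nrow(gold) > 0L) {
    known_ids <- unique(c(gold$gene_id, gold$disease_id))
    missing <- setdiff(known_ids, c(genes, diseases))
    if (length(missing) > 0L) {
      abort(sprintf("gold standard references unknown entity id(s): %s",
                    paste(missing, collapse = ", ")))
    }
  }
  prof <- profiles$profiles
  kws <- sort(unique(prof$keyword))
  kw_index <- stats::setNames(seq_along(kws), kws)
  if (length(kws) == 0L) {
    cos <- matrix(0, nrow = length(genes), ncol = length(diseases))
    g_norm <- numeric(length(genes))
    d_norm <- numeric(length(diseases))
  } else {
    G <- profile_matrix(prof[prof$kind == "gene", ], kw_index, genes)
    D <- profile_matrix(prof[prof$kind == "disease", ], kw_index, diseases)
    g_norm <- sqrt(Matrix::colSums(G^2))
    d_norm <- sqrt(Matrix::colSums(D^2))
    cos <- as.matrix(Matrix::crossprod(G, D))
    denom <- outer(g_norm, d_norm)
    nz <- denom > 0
    cos[nz] <- cos[nz] / denom[nz]
    cos[!nz] <- 0
  }
  out <- tidyr::expand_grid(gene_id = genes, disease_id = diseases) %>%
    dplyr::mutate(
      cosine = as.numeric(cos[cbind(match(.data$gene_id, genes),
                                    match(.data$disease_id, diseases))]),
      degenerate = g_norm[match(.data$gene_id, genes)] == 0 |
        d_norm[match(.data$disease_id, diseases)] == 0) %>%
    dplyr::arrange(.data$gene_id, .data$disease_id)
  out <- apply_gold(out, gold)
  out <- dplyr::select(out, "gene_id", "disease_id", "cosine", "is_known",
                       "degenerate")
  class(out) <- unique(c("gda_assoc", class(out)))
  out
}

# Set/refresh the is_known flag from a gold tibble (NULL -> all FALSE).
apply_gold <- function(table, gold) {
  if (is.null(gold) || nrow(gold) == 0L) {
    table$is_known <- FALSE
  } else {
    key <- paste(table$gene_id, table$disease_id, sep = "\r")
    gkey <- unique(paste(gold$gene_id, gold$disease_id, sep = "\r"))
    table$is_known <- key %in% gkey
  }
  table
}

#' Bin the cosine score distribution
#'
#' Half-open bins `[e_i, e_{i+1})`, last bin closed, so a score of exactly 1
#' is counted. The default edges focus resolution near 0, where the bulk of
#' gene-disease pairs sit.
#'
#' @param table A `gda_assoc` tibble.
#' @param edges Ascending numeric bin edges spanning the score range.
#' @return A tibble with columns `bin_low`, `bin_high`, `label`, `count`,
#'   `proportion`; proportions sum to 1 when the table is non-empty.
#' @export
bin_distribution <- function(table,
                             edges = c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1)) {
  if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE)) {
    abort("`edges` must be strictly ascending with at least two values")
  }
  k <- length(edges) - 1L
  bin <- findInterval(table$cosine, edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), k)
  counts <- tabulate(bin, nbins = k)
  tibble(bin_low = edges[-length(edges)],
         bin_high = edges[-1],
         label = sprintf("[%g,%g%s", edges[-length(edges)], edges[-1],
                         c(rep(")", k - 1L), "]")),
         count = counts,
         proportion = if (nrow(table) > 0L) counts / nrow(table) else
           rep(NA_real_, k))
}

#' Write / read an association table TSV
#'
#' Columns `gene_id<TAB>disease_id<TAB>cosine<TAB>is_known<TAB>degenerate`,
#' cosine printed with 6 decimals.
#'
#' @param table A `gda_assoc` tibble.
#' @param path File path.
#' @return `path` (write) or the table (read).
#' @export
write_association <- function(table, path) {
  out <- dplyr::mutate(table, cosine = sprintf("%.6f", .data$cosine))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_association
#' @export
read_association <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    disease_id = readr::col_character(),
    cosine = readr::col_double(),
    is_known = readr::col_logical(),
    degenerate = readr::col_logical()))
  class(out) <- unique(c("gda_assoc", class(out)))
  out
}
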