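#' Run the full literature-mining pipeline on a study
#'
#' Wires the stages together: corpus assembly (entity matching and
#' filtering), per-(document, entity) vectorization with location weights,
#' corpus-level term weighting (IDF x depth penalty), profile aggregation,
#' all-pairs cosine scoring, and precision/recall evaluation against the
#' study's gold standard.
#'
#' @param study A `sim_study` from [generate_study()] / [read_study()], or
#'   any list with elements `dictionary`, `records`, `gene_lexicon`,
#'   `disease_lexicon`, `gold`.
#' @param weights A [weight_config()]; use [uniform_weights()] to ablate the
#'   location weight matrix.
#' @param norm_method `"log"` (default) or `"sum1"` document-vector
#'   normalization.
#' @param use_pwk Apply the MeSH depth penalty in term weighting? Default
#'   `TRUE`.
#' @param depth_rule `"max"` or `"min"` multi-position depth aggregation.
#' @param idf_scope `"split"` (separate gene / disease corpora, the default)
#'   or `"joint"` (pooled).
#' @param thresholds Ascending threshold grid for the PR sweep.
#' @param bin_edges Bin edges for the score distribution.
#' @return A list of class `gda_result` with elements `associations`
#'   (`gda_assoc`), `pr` (`gda_pr_curve`), `bins`, `term_weights` (list with
#'   `gene` and `disease`), `profiles`, `corpus`, `gold` and `options`.
#' @export
#' @examples
#' study <- generate_study(sim_config(n_genes = 4, n_diseases = 3,
#'                                    n_known_pairs = 2, seed = 7))
#' res <- gda_run(study)
#' glance(res)
gda_run <- function(study, weights = weight_config(),
                    norm_method = c("log", "sum1"), use_pwk = TRUE,
                    depth_rule = c("max", "min"),
                    idf_scope = c("split", "joint"),
                    thresholds = seq(0, 1, by = 0.01),
                    bin_edges = c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1)) {
  norm_method <- match.arg(norm_method)
  depth_rule <- match.arg(depth_rule)
  idf_scope <- match.arg(idf_scope)
  corpus <- build_corpus(study$records, study$gene_lexicon,
                         study$disease_lexicon)
  dv <- vectorize_corpus(corpus, study$dictionary, weights, norm_method)
  if (idf_scope == "split") {
    tw_g <- term_weights(corpus_sums(dplyr::filter(dv, .data$kind == "gene")),
                         study$dictionary, use_pwk, depth_rule)
    tw_d <- term_weights(corpus_sums(dplyr::filter(dv, .data$kind == "disease")),
                         study$dictionary, use_pwk, depth_rule)
  } else {
    tw_g <- term_weights(corpus_sums(dv), study$dictionary, use_pwk,
                         depth_rule)
    tw_d <- tw_g
  }
  profiles <- build_all_profiles(dv, tw_g, tw_d,
                                 study$gene_lexicon$entity_id,
                                 study$disease_lexicon$entity_id)
  assoc <- score_all(profiles, study$gold)
  out <- list(
    associations = assoc,
    pr = pr_curve(assoc, thresholds),
    bins = bin_distribution(assoc, bin_edges),
    term_weights = list(gene = tw_g, disease = tw_d),
    profiles = profiles,
    corpus = corpus,
    gold = study$gold,
    options = list(weights = unclass(weights), norm_method = norm_method,
                   use_pwk = use_pwk, depth_rule = depth_rule,
                   idf_scope = idf_scope))
  class(out) <- "gda_result"
  out
}

#' Precision of the top-k ranked pairs
#'
#' Ranks pairs by cosine (descending; ties broken by gene then disease id for
#' determinism) and reports the fraction of the first `k` that are
#' gold-standard linkages.
#'
#' @param table A `gda_assoc` tibble.
#' @param k Number of top pairs (defaults to the number of known pairs).
#' @return A single number in [0, 1].
#' @export
precision_top_k <- function(table, k = sum(table$is_known)) {
  if (k < 1L || k > nrow(table)) {
    abort("`k` must lie between 1 and the number of pairs")
  }
  ranked <- dplyr::arrange(table, dplyr::desc(.data$cosine), .data$gene_id,
                           .data$disease_id)
  mean(ranked$is_known[seq_len(k)])
}

#' @export
print.gda_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0("<gda_result> %d genes x %d diseases = %d pairs ",
                     "(%d known, %d degenerate)\n"),
              g$n_genes, g$n_diseases, g$n_pairs, g$n_known, g$n_degenerate))
  cat(sprintf("  median cosine: known %.4f, unknown %.4f; top-%d precision %.3f\n",
              g$median_cosine_known, g$median_cosine_unknown, g$n_known,
              g$precision_top_k))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pipeline result into its association table
#'
#' @param x A `gda_result`.
#' @param ... Unused.
#' @return The `gda_assoc` tibble of scored pairs.
#' @export
#' @method tidy gda_result
tidy.gda_result <- function(x, ...) {
  x$associations
}

#' One-row summary of a pipeline result
#'
#' @param x A `gda_result`.
#' @param ... Unused.
#' @return A one-row tibble: pair counts, known/unknown median cosine,
#'   top-|K| precision, and recall at threshold 0.5.
#' @export
#' @method glance gda_result
glance.gda_result <- function(x, ...) {
  a <- x$associations
  known <- a$cosine[a$is_known]
  unknown <- a$cosine[!a$is_known]
  tibble(
    n_genes = length(unique(a$gene_id)),
    n_diseases = length(unique(a$disease_id)),
    n_pairs = nrow(a),
    n_known = sum(a$is_known),
    n_degenerate = sum(a$degenerate),
    median_cosine_known = stats::median(known),
    median_cosine_unknown = stats::median(unknown),
    precision_top_k = if (sum(a$is_known) > 0L) {
      precision_top_k(a)
    } else {
      NA_real_
    },
    recall_at_0.5 = if (sum(a$is_known) > 0L) recall_at(a, 0.5) else NA_real_)
}
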