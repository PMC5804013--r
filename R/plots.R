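#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a precision-recall sweep
#'
#' @param object A `gda_pr_curve` tibble from [pr_curve()].
#' @param ... Unused.
#' @return A ggplot: precision against recall, points ordered by threshold;
#'   undefined (empty-denominator) points are dropped.
#' @export
#' @method autoplot gda_pr_curve
autoplot.gda_pr_curve <- function(object, ...) {
  dat <- dplyr::filter(object, !is.na(.data$precision))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = "Precision-recall over the cosine threshold sweep") +
    ggplot2::theme_minimal()
}

#' Plot score distributions of known vs unknown pairs
#'
#' @param object A `gda_assoc` tibble from [score_all()].
#' @param ... Unused.
#' @return A ggplot histogram of cosine scores, filled by gold-standard
#'   membership.
#' @export
#' @method autoplot gda_assoc
autoplot.gda_assoc <- function(object, ...) {
  dat <- dplyr::mutate(object,
                       status = ifelse(.data$is_known, "known", "unknown"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cosine, fill = .data$status)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "Cosine similarity", y = "Pairs", fill = NULL,
                  title = "Gene-disease cosine similarity") +
    ggplot2::theme_minimal()
}

#' Bar chart of the binned score distribution
#'
#' @param bins A tibble from [bin_distribution()].
#' @return A ggplot bar chart of per-bin proportions.
#' @export
plot_score_bins <- function(bins) {
  dat <- dplyr::mutate(bins, label = factor(.data$label,
                                            levels = .data$label))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, y = .data$proportion)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Cosine similarity bin", y = "Proportion of pairs",
                  title = "Distribution of gene-disease cosine similarities") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
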