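#' Read a gold-standard linkage table
#'
#' TSV with columns `gene_id<TAB>disease_id`; `#` starts a comment line.
#' Duplicate pairs collapse to one.
#'
#' @param path File path.
#' @return A tibble with columns `gene_id`, `disease_id`.
#' @export
read_gold <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  rows <- purrr::imap(lines, function(line, i) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      abort(sprintf("malformed gold-standard line %d: expected gene_id<TAB>disease_id", i))
    }
    tibble(gene_id = trimws(parts[1]), disease_id = trimws(parts[2]))
  })
  dplyr::bind_rows(rows) %>% dplyr::distinct()
}

#' Write a gold-standard linkage table
#'
#' @param gold A tibble with columns `gene_id`, `disease_id`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  readr::write_lines(paste0(gold$gene_id, "\t", gold$disease_id), path)
  invisible(path)
}

resolve_known <- function(table, gold) {
  if (!is.null(gold)) {
    table <- apply_gold(table, gold)
  }
  if (is.null(table$is_known)) {
    abort("association table has no `is_known` flag and no gold standard was given")
  }
  table
}

#' Precision of prediction at a cosine threshold
#'
#' \deqn{P(x) = \frac{|\{(g,d): \cos \ge x\} \cap K|}{|\{(g,d): \cos \ge x\}|}}
#' The threshold is inclusive. When no pair scores at or above `x` the
#' quantity is undefined and `NA` is returned.
#'
#' @param table A `gda_assoc` tibble.
#' @param x Threshold in [0, 1].
#' @param gold Optional gold tibble; if omitted the table's `is_known` flag
#'   is used.
#' @return Precision in [0, 1], or `NA` for an empty denominator.
#' @export
precision_at <- function(table, x, gold = NULL) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort("`x` must be a single threshold in [0, 1]")
  }
  table <- resolve_known(table, gold)
  above <- table$cosine >= x
  n <- sum(above)
  if (n == 0L) {
    return(NA_real_)
  }
  sum(above & table$is_known) / n
}

#' Recall of prediction at a cosine threshold
#'
#' \deqn{R(x) = \frac{|\{(g,d): \cos \ge x\} \cap K|}{|K|}}
#' Inclusive threshold; errors when the gold set is empty.
#'
#' @inheritParams precision_at
#' @return Recall in [0, 1].
#' @export
recall_at <- function(table, x, gold = NULL) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort("`x` must be a single threshold in [0, 1]")
  }
  table <- resolve_known(table, gold)
  n_known <- sum(table$is_known)
  if (n_known == 0L) {
    abort("gold standard is empty: recall is undefined")
  }
  sum(table$cosine >= x & table$is_known) / n_known
}

#' Precision-recall sweep over a threshold grid
#'
#' One point per threshold via [precision_at()] and [recall_at()]; no
#' interpolation. Recall is non-increasing in the threshold by set nesting.
#'
#' @param table A `gda_assoc` tibble.
#' @param thresholds Ascending thresholds in [0, 1]; default 0 to 1 in steps
#'   of 0.01.
#' @param gold Optional gold tibble.
#' @return A tibble of class `gda_pr_curve` with columns `threshold`,
#'   `precision` (`NA` where undefined), `recall`, `n_above`.
#' @export
pr_curve <- function(table, thresholds = seq(0, 1, by = 0.01), gold = NULL) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("`thresholds` must be strictly ascending")
  }
  table <- resolve_known(table, gold)
  n_known <- sum(table$is_known)
  if (n_known == 0L) {
    abort("gold standard is empty: recall is undefined")
  }
  pts <- purrr::map(thresholds, function(x) {
    above <- table$cosine >= x
    n <- sum(above)
    hit <- sum(above & table$is_known)
    tibble(threshold = x,
           precision = if (n > 0L) hit / n else NA_real_,
           recall = hit / n_known,
           n_above = n)
  })
  out <- dplyr::bind_rows(pts)
  class(out) <- unique(c("gda_pr_curve", class(out)))
  out
}

#' Fraction of known pairs within score ranges
#'
#' For each half-open range `[e_i, e_{i+1})` (last range closed), the
#' fraction of pairs falling in it that are gold-standard linkages; `NA` for
#' empty ranges.
#'
#' @param table A `gda_assoc` tibble.
#' @param edges Ascending numeric range edges.
#' @param gold Optional gold tibble.
#' @return A tibble with columns `bin_low`, `bin_high`, `n_pairs`, `n_known`,
#'   `proportion_known`.
#' @export
precision_in_ranges <- function(table,
                                edges = c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1),
                                gold = NULL) {
  if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE)) {
    abort("`edges` must be strictly ascending with at least two values")
  }
  table <- resolve_known(table, gold)
  k <- length(edges) - 1L
  bin <- findInterval(table$cosine, edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), k)
  n_pairs <- tabulate(bin, nbins = k)
  n_known <- tabulate(bin[table$is_known], nbins = k)
  tibble(bin_low = edges[-length(edges)],
         bin_high = edges[-1],
         n_pairs = n_pairs,
         n_known = n_known,
         proportion_known = ifelse(n_pairs > 0, n_known / n_pairs, NA_real_))
}

#' Write a PR curve TSV
#'
#' Columns `threshold<TAB>precision<TAB>recall<TAB>n_above`; undefined
#' precision written as `NA`.
#'
#' @param curve A `gda_pr_curve` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pr_curve <- function(curve, path) {
  readr::write_tsv(curve, path, na = "NA")
  invisible(path)
}
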