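# Independent oracles and small fixture builders shared across the suite.

# Brute-force keyword matcher: scans token positions left to right comparing
# raw token vectors (no hashing / canonical-string lookup), longest match
# first, non-overlapping. Independent of the package's phrase-index path.
oracle_match <- function(text, keywords) {
  toks <- strsplit(gsub("[^a-z0-9]+", " ", tolower(text)), " ")[[1]]
  toks <- toks[nzchar(toks)]
  kw_toks <- lapply(tolower(keywords), function(k) {
    t <- strsplit(gsub("[^a-z0-9]+", " ", k), " ")[[1]]
    t[nzchar(t)]
  })
  names(kw_toks) <- keywords
  counts <- integer(0)
  i <- 1
  while (i <= length(toks)) {
    best <- NULL
    best_len <- 0
    for (k in names(kw_toks)) {
      kt <- kw_toks[[k]]
      L <- length(kt)
      if (L > best_len && i + L - 1 <= length(toks) &&
          identical(toks[i:(i + L - 1)], kt)) {
        best <- k
        best_len <- L
      }
    }
    if (is.null(best)) {
      i <- i + 1
    } else {
      counts[best] <- (if (best %in% names(counts)) counts[best] else 0L) + 1L
      i <- i + best_len
    }
  }
  counts
}

# Dense cosine recomputation over the union support.
oracle_cosine <- function(u, v) {
  keys <- union(names(u), names(v))
  ud <- vd <- numeric(length(keys))
  names(ud) <- names(vd) <- keys
  ud[names(u)] <- u
  vd[names(v)] <- v
  nu <- sqrt(sum(ud^2))
  nv <- sqrt(sum(vd^2))
  if (nu == 0 || nv == 0) return(0)
  sum(ud * vd) / (nu * nv)
}

# Naive per-threshold recount of precision/recall.
oracle_pr_point <- function(cosine, is_known, x) {
  above <- which(cosine >= x)
  hit <- sum(is_known[above])
  list(precision = if (length(above) > 0) hit / length(above) else NA_real_,
       recall = hit / sum(is_known),
       n_above = length(above))
}

# Random sparse non-negative named vector over a keyword alphabet.
random_sparse_vec <- function(n_max = 12, alphabet = paste0("k", 1:30)) {
  n <- sample.int(n_max, 1)
  keys <- sample(alphabet, n)
  stats::setNames(round(stats::runif(n, 0.01, 5), 4), keys)
}

# Random association table with a random gold subset.
random_assoc_table <- function(n_rows = 100) {
  tbl <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n_rows)),
    disease_id = sprintf("d%03d", sample.int(max(3, n_rows %/% 4), n_rows,
                                             replace = TRUE)),
    cosine = round(stats::runif(n_rows), 3),
    is_known = stats::runif(n_rows) < 0.25,
    degenerate = FALSE)
  if (!any(tbl$is_known)) tbl$is_known[1] <- TRUE
  class(tbl) <- unique(c("gda_assoc", class(tbl)))
  tbl
}

# Hand-built entity_profiles object from named lists of named vectors.
make_profiles <- function(genes, diseases) {
  to_tbl <- function(lst, kind) {
    rows <- lapply(names(lst), function(id) {
      v <- lst[[id]]
      if (length(v) == 0) return(NULL)
      tibble::tibble(entity_id = id, kind = kind, keyword = names(v),
                     weight = unname(v))
    })
    dplyr::bind_rows(rows)
  }
  meta <- dplyr::bind_rows(
    tibble::tibble(entity_id = names(genes), kind = "gene",
                   n_docs = ifelse(lengths(genes) > 0, 1L, 0L)),
    tibble::tibble(entity_id = names(diseases), kind = "disease",
                   n_docs = ifelse(lengths(diseases) > 0, 1L, 0L)))
  out <- list(profiles = to_tbl(genes, "gene") %>%
                dplyr::bind_rows(to_tbl(diseases, "disease")),
              meta = meta)
  class(out) <- "entity_profiles"
  out
}

# A 3-keyword dictionary tibble usable wherever a mesh_dict is expected.
toy_dict <- function() {
  tibble::tibble(
    keyword = c("neoplasms", "lung neoplasms", "anemia"),
    tree_number = c("C04", "C04.588.894", "C15.378"),
    category = "C",
    depth = c(2L, 4L, 3L))
}

`%>%` <- dplyr::`%>%`
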