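test_that("cosine similarity matches hand values and flags degenerates", {
  expect_equal(cosine_similarity(c(a = 0.3, b = 0.7), c(a = 0.3, b = 0.7)), 1)
  expect_equal(cosine_similarity(c(a = 1), c(b = 1)), 0)
  expect_equal(cosine_similarity(c(a = 1, b = 2), c(a = 2, b = 1)), 0.8)
  expect_equal(cosine_similarity(stats::setNames(numeric(0), character(0)),
                                 c(a = 1)), 0)
  expect_error(cosine_similarity(c(a = -1), c(a = 1)), "non-negative")
})

test_that("cosine is symmetric, scale-invariant and Cauchy-Schwarz bounded", {
  set.seed(17)
  for (i in 1:100) {
    u <- random_sparse_vec()
    v <- random_sparse_vec()
    cuv <- cosine_similarity(u, v)
    expect_equal(cuv, cosine_similarity(v, u))
    expect_equal(cosine_similarity(3.7 * u, v), cuv, tolerance = 1e-12)
    expect_lte(cuv, 1 + 1e-12)
    expect_gte(cuv, 0)
    # dense recomputation oracle
    expect_equal(cuv, oracle_cosine(u, v), tolerance = 1e-12)
  }
})

test_that("score_all covers the cross-product with degenerate zeros", {
  prof <- make_profiles(
    genes = list(g1 = c(a = 1, b = 2), g2 = stats::setNames(numeric(0),
                                                            character(0))),
    diseases = list(d1 = c(a = 2, b = 1), d2 = c(c = 1),
                    d3 = c(a = 1, b = 2)))
  tbl <- score_all(prof)
  expect_equal(nrow(tbl), 6L) # 2 genes x 3 diseases
  expect_equal(tbl$gene_id, rep(c("g1", "g2"), each = 3))
  expect_equal(tbl$cosine[tbl$gene_id == "g1" & tbl$disease_id == "d1"], 0.8)
  expect_equal(tbl$cosine[tbl$gene_id == "g1" & tbl$disease_id == "d3"], 1)
  # empty gene profile scores 0 everywhere and is flagged
  g2 <- tbl[tbl$gene_id == "g2", ]
  expect_true(all(g2$cosine == 0))
  expect_true(all(g2$degenerate))
  expect_false(any(tbl$degenerate[tbl$gene_id == "g1"]))
  # gold flags and unknown-id error
  tbl2 <- score_all(prof, gold = tibble::tibble(gene_id = "g1",
                                                disease_id = "d3"))
  expect_equal(sum(tbl2$is_known), 1L)
  expect_error(score_all(prof, gold = tibble::tibble(gene_id = "gX",
                                                     disease_id = "d1")),
               "gX")
})

test_that("matrix scoring equals the per-pair cosine oracle", {
  set.seed(23)
  genes <- stats::setNames(lapply(1:10, function(i) random_sparse_vec()),
                           sprintf("g%02d", 1:10))
  diseases <- stats::setNames(lapply(1:10, function(i) random_sparse_vec()),
                              sprintf("d%02d", 1:10))
  tbl <- score_all(make_profiles(genes, diseases))
  for (r in seq_len(nrow(tbl))) {
    expect_equal(tbl$cosine[r],
                 oracle_cosine(genes[[tbl$gene_id[r]]],
                               diseases[[tbl$disease_id[r]]]),
                 tolerance = 1e-12)
  }
})

test_that("score binning uses half-open bins with a closed last bin", {
  tbl <- tibble::tibble(cosine = c(0.005, 0.015, 0.5))
  b <- bin_distribution(tbl, edges = c(0, 0.01, 0.02, 1))
  expect_equal(b$count, c(1L, 1L, 1L))
  expect_equal(sum(b$proportion), 1, tolerance = 1e-12)
  # all-zero scores collapse into the first bin
  z <- bin_distribution(tibble::tibble(cosine = rep(0, 5)),
                        edges = c(0, 0.5, 1))
  expect_equal(z$count, c(5L, 0L))
  # an exact 1.0 lands in the final closed bin
  one <- bin_distribution(tibble::tibble(cosine = 1), edges = c(0, 0.5, 1))
  expect_equal(one$count, c(0L, 1L))
  expect_error(bin_distribution(tbl, edges = c(0, 0.5, 0.2)), "ascending")
  set.seed(29)
  rt <- random_assoc_table(150)
  br <- bin_distribution(rt)
  expect_equal(sum(br$count), nrow(rt))
  expect_equal(sum(br$proportion), 1, tolerance = 1e-12)
})

test_that("association tables round-trip through the TSV format", {
  tbl <- random_assoc_table(20)
  path <- withr::local_tempfile()
  write_association(tbl, path)
  back <- read_association(path)
  expect_equal(back$gene_id, tbl$gene_id)
  expect_equal(back$cosine, tbl$cosine, tolerance = 1e-6)
  expect_equal(back$is_known, tbl$is_known)
})
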