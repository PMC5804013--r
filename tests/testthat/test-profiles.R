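test_that("a profile is the term-weighted sum of document vectors", {
  tw <- tibble::tibble(keyword = c("a", "b"), sum_w = c(4, 1),
                       depth = c(9L, 9L), idf = c(0.5, 2), pwk = c(1, 1),
                       tw = c(0.5, 2))
  p1 <- build_profile(tibble::tibble(doc_id = "1", keyword = "a",
                                     weight = 1.0), tw)
  expect_equal(stats::setNames(p1$weight, p1$keyword), c(a = 0.5))
  p2 <- build_profile(tibble::tibble(doc_id = c("1", "2"), keyword = "a",
                                     weight = c(0.4, 0.6)),
                      tibble::tibble(keyword = "a", tw = 2))
  expect_equal(p2$weight, 2.0) # (0.4 + 0.6) * 2
  expect_equal(attr(p2, "n_docs"), 2L)
  # dense accumulate-then-scale oracle on random vectors
  set.seed(5)
  vecs <- lapply(1:20, function(i) random_sparse_vec())
  dv <- dplyr::bind_rows(lapply(seq_along(vecs), function(i) {
    tibble::tibble(doc_id = as.character(i), keyword = names(vecs[[i]]),
                   weight = unname(vecs[[i]]))
  }))
  keys <- sort(unique(dv$keyword))
  tw_rand <- tibble::tibble(keyword = keys,
                            tw = round(stats::runif(length(keys), 0.1, 3), 3))
  dense <- stats::setNames(numeric(length(keys)), keys)
  for (v in vecs) for (k in names(v)) dense[k] <- dense[k] + v[[k]]
  dense <- dense * stats::setNames(tw_rand$tw, tw_rand$keyword)[names(dense)]
  got <- build_profile(dv, tw_rand)
  expect_equal(stats::setNames(got$weight, got$keyword), dense)
})

test_that("every lexicon entity gets a profile, empty ones included", {
  dv <- tibble::tibble(entity_id = c("g1", "g1", "g2"),
                       kind = "gene",
                       doc_id = c("1", "2", "3"),
                       keyword = c("a", "a", "b"),
                       weight = c(0.5, 0.5, 1))
  tw <- tibble::tibble(keyword = c("a", "b"), tw = c(1, 2))
  prof <- build_all_profiles(dv, tw, tw, c("g1", "g2", "g3"), "d1")
  expect_equal(nrow(prof$meta), 4L)
  expect_equal(prof$meta$n_docs[prof$meta$entity_id == "g3"], 0L)
  expect_false("g3" %in% prof$profiles$entity_id)
  # disjoint document sets -> no shared contributions
  g1 <- prof$profiles[prof$profiles$entity_id == "g1", ]
  g2 <- prof$profiles[prof$profiles$entity_id == "g2", ]
  expect_equal(g1$keyword, "a")
  expect_equal(g2$keyword, "b")
  expect_equal(g1$weight, 1) # (0.5+0.5)*1
  expect_equal(g2$weight, 2)
  # all entries are non-negative
  expect_true(all(prof$profiles$weight >= 0))
})

test_that("profiles are permutation-invariant and homogeneous in doc scale", {
  set.seed(13)
  dv <- tibble::tibble(
    entity_id = "g1", kind = "gene",
    doc_id = as.character(rep(1:6, each = 4)),
    keyword = sample(paste0("k", 1:8), 24, replace = TRUE),
    weight = stats::runif(24))
  tw <- tibble::tibble(keyword = paste0("k", 1:8),
                       tw = stats::runif(8, 0.5, 2))
  p <- build_all_profiles(dv, tw, tw, "g1", character(0))
  p_shuf <- build_all_profiles(dv[sample(nrow(dv)), ], tw, tw, "g1",
                               character(0))
  expect_equal(p$profiles, p_shuf$profiles)
  dv_scaled <- dplyr::mutate(dv, weight = 3 * weight)
  p_scaled <- build_all_profiles(dv_scaled, tw, tw, "g1", character(0))
  expect_equal(p_scaled$profiles$weight, 3 * p$profiles$weight)
})

test_that("planted signatures dominate profile mass on synthetic studies", {
  cfg <- sim_config(n_genes = 6, n_diseases = 3, n_known_pairs = 3,
                    docs_per_entity = 4, noise_rate = 0.1, seed = 21)
  study <- generate_study(cfg)
  corp <- build_corpus(study$records, study$gene_lexicon,
                       study$disease_lexicon)
  dv <- vectorize_corpus(corp, study$dictionary)
  tw <- term_weights(corpus_sums(dplyr::filter(dv, kind == "gene")),
                     study$dictionary)
  prof <- build_all_profiles(dplyr::filter(dv, kind == "gene"), tw, tw,
                             study$gene_lexicon$entity_id, character(0))
  for (g in study$gene_lexicon$entity_id) {
    rows <- prof$profiles[prof$profiles$entity_id == g, ]
    planted <- sum(rows$weight[rows$keyword %in% study$signatures[[g]]])
    expect_gt(planted / sum(rows$weight), 0.5)
  }
})
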