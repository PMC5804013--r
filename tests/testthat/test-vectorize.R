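test_that("location vectors separate title, sentence and binary MeSH counts", {
  dict <- toy_dict()
  lv <- build_location_vectors("Neoplasms revisited",
                               c("No keyword here.", "Anemia and anemia."),
                               c("Neoplasms", "Neoplasms"), dict)
  expect_equal(lv$title, c(neoplasms = 1L))
  expect_equal(length(lv$sentences[[1]]), 0L)
  expect_equal(lv$sentences[[2]], c(anemia = 2L))
  # MeSH vector is binary even when the term is listed twice
  expect_equal(lv$mesh, c(neoplasms = 1L))
  # empty abstract -> no sentence vectors
  lv2 <- build_location_vectors("x", character(0), character(0), dict)
  expect_equal(lv2$sentences, list())
})

test_that("combination applies the location weights and co-mention upgrade", {
  dict <- toy_dict()
  w <- weight_config() # MeSH 3, title 2, abstract-with 2, abstract-without 1
  # k once in title only -> 2
  lv <- build_location_vectors("neoplasms", character(0), character(0), dict)
  raw <- combine_locations(lv, w)
  expect_equal(raw$weight, 2)
  # k once in a co-mentioning sentence and once in a plain one -> 2 + 1
  lv2 <- build_location_vectors("none", c("anemia first.", "anemia again."),
                                character(0), dict)
  raw2 <- combine_locations(lv2, w, entity_sentences = 1L)
  expect_equal(raw2$weight[raw2$keyword == "anemia"], 3)
  # k in MeSH terms only -> 3
  lv3 <- build_location_vectors("none", character(0), "anemia", dict)
  expect_equal(combine_locations(lv3, w)$weight, 3)
  expect_error(weight_config(0, 0, 0, 0), "at least one")
  expect_error(weight_config(-1, 1, 1, 1), ">= 0")
})

test_that("normalization scales to unit sum under both methods", {
  raw <- c(a = 2, b = 3, c = 5)
  s <- normalize_vector(raw, "sum1")
  expect_equal(stats::setNames(s$weight, s$keyword), c(a = 0.2, b = 0.3, c = 0.5))
  one <- normalize_vector(c(a = 1), "sum1")
  expect_equal(one$weight, 1)
  expect_equal(normalize_vector(c(a = 1), "log")$weight, 1)
  lg <- normalize_vector(c(a = 1, b = 3), "log")
  expect_equal(stats::setNames(lg$weight, lg$keyword),
               c(a = 1 / 3, b = 2 / 3)) # log2/(log2+log4), log4/(log2+log4)
  expect_equal(nrow(normalize_vector(stats::setNames(numeric(0), character(0)),
                                     "log")), 0L)
  expect_error(normalize_vector(c(a = -1), "sum1"), "non-negative")
})

test_that("non-empty vectors sum to one and combine is weight-homogeneous", {
  set.seed(7)
  for (i in 1:50) {
    raw <- random_sparse_vec()
    for (method in c("sum1", "log")) {
      v <- normalize_vector(raw, method)
      expect_equal(sum(v$weight), 1, tolerance = 1e-9)
    }
  }
  dict <- toy_dict()
  lv <- build_location_vectors("Neoplasms and anemia",
                               c("Lung neoplasms spread.", "Anemia persisted."),
                               "anemia", dict)
  w1 <- weight_config(3, 2, 2, 1)
  w2 <- weight_config(6, 4, 4, 2)
  r1 <- combine_locations(lv, w1, entity_sentences = 2L)
  r2 <- combine_locations(lv, w2, entity_sentences = 2L)
  # doubling every weight doubles every raw entry ...
  expect_equal(r2$weight, 2 * r1$weight)
  expect_equal(r2$keyword, r1$keyword)
  # ... and leaves the sum-normalized vector unchanged
  expect_equal(normalize_vector(r1, "sum1"), normalize_vector(r2, "sum1"))
})

test_that("log transform compresses the dynamic range", {
  set.seed(11)
  for (i in 1:100) {
    raw <- random_sparse_vec()
    if (length(raw) < 2) next
    before <- max(raw) / min(raw)
    lg <- normalize_vector(raw, "log")$weight
    after <- max(lg) / min(lg)
    expect_lte(after, before + 1e-12)
  }
})

test_that("keywords absent from every location never enter the vector", {
  dict <- toy_dict()
  corp <- build_corpus(
    tibble::tibble(doc_id = "1", title = "brca1 neoplasms",
                   abstract = "Anemia noted.", mesh = list(character(0))),
    tibble::tibble(entity_id = "g1", name = "brca1"),
    tibble::tibble(entity_id = "d1", name = "malady"))
  dv <- vectorize_corpus(corp, dict)
  expect_setequal(dv$keyword, c("neoplasms", "anemia"))
  expect_false("lung neoplasms" %in% dv$keyword)
  expect_equal(sum(dv$weight), 1, tolerance = 1e-9)
})
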