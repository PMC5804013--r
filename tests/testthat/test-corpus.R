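test_that("jsonl records round-trip and duplicates are skipped", {
  path <- withr::local_tempfile(lines = c(
    '{"id":"1","title":"T one","abstract":"A one. B one.","mesh":["Neoplasms"]}',
    '{"id":"2","title":"T two","abstract":"A two.","mesh":[]}',
    '{"id":"1","title":"T dup","abstract":"x","mesh":[]}'))
  expect_warning(recs <- read_corpus(path, "jsonl"), "duplicate")
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$title[recs$doc_id == "1"], "T one")
  expect_equal(recs$mesh[[1]], "Neoplasms")
})

test_that("MEDLINE XML records carry all four fields", {
  xml <- system.file("extdata", "corpus_sample.xml", package = "litgda")
  expect_message(recs <- read_corpus(xml, "medline_xml"), "no abstract")
  expect_equal(recs$doc_id, c("100001", "100002", "100003"))
  expect_match(recs$title[1], "BRCA1")
  expect_equal(recs$mesh[[2]], c("Lung Neoplasms", "Doxorubicin"))
  # title-only record kept with empty abstract
  expect_equal(recs$abstract[3], "")
})

test_that("sentence splitting is rule-based with an abbreviation guard", {
  expect_equal(split_sentences(""), character(0))
  expect_equal(split_sentences("A result. Another result."),
               c("A result.", "Another result."))
  expect_equal(split_sentences("E. coli causes disease."),
               "E. coli causes disease.")
  expect_equal(split_sentences("Seen in E. Coli strains. Also elsewhere."),
               c("Seen in E. Coli strains.", "Also elsewhere."))
  expect_equal(split_sentences("Counts rose 3.5 fold."), "Counts rose 3.5 fold.")
  expect_equal(length(split_sentences("One? Two! Three.")), 3L)
  # concatenation covers the input (modulo separators) and no empties
  txt <- "First point. Second point has 2 parts. Third."
  ss <- split_sentences(txt)
  expect_false(any(!nzchar(ss)))
  expect_equal(paste(ss, collapse = " "), txt)
})

test_that("keyword matching is longest-match-first on token boundaries", {
  dict <- c("neoplasms", "lung neoplasms")
  m <- match_keywords("neoplasms of the lung", dict)
  expect_equal(m$keyword, "neoplasms")
  expect_equal(m$count, 1L)
  m2 <- match_keywords("lung neoplasms and neoplasms", dict)
  expect_equal(m2[m2$keyword == "lung neoplasms", ]$count, 1L)
  expect_equal(m2[m2$keyword == "neoplasms", ]$count, 1L)
  expect_equal(nrow(match_keywords("", dict)), 0L)
  # case/punctuation-insensitive
  m3 <- match_keywords("Lung-Neoplasms!", dict)
  expect_equal(m3$keyword, "lung neoplasms")
})

test_that("keyword matching agrees with a brute-force oracle on random texts", {
  set.seed(42)
  alphabet <- c("alpha", "beta", "gamma", "delta", "eps", "zeta", "eta")
  kws <- c("alpha", "alpha beta", "beta gamma", "gamma", "delta",
           "delta eps zeta", "eta", "beta", "zeta eta", "eps")
  for (i in 1:100) {
    text <- paste(sample(alphabet, 30, replace = TRUE), collapse = " ")
    got <- match_keywords(text, kws)
    want <- oracle_match(text, kws)
    want <- want[order(names(want))]
    expect_equal(got$keyword, names(want), info = text)
    expect_equal(got$count, unname(as.integer(want)), info = text)
  }
})

test_that("entity mentions record field and sentence index with set semantics", {
  lex <- tibble::tibble(entity_id = c("g1", "g1", "d1"),
                        name = c("brca1", "brca-1", "breast cancer"))
  m <- match_entities("BRCA1 in cancer", character(0), character(0), lex)
  expect_equal(m$entity_id, "g1")
  expect_equal(m$field, "title")
  sents <- c("BRCA1 was mutated.", "Controls were clean.",
             "Both BRCA1 and BRCA-1 spellings occur.")
  m2 <- match_entities("none here", sents, character(0), lex)
  expect_equal(m2$sentence, c(1L, 3L)) # two synonyms in one sentence = one row
  m3 <- match_entities("x", character(0), c("Breast Cancer"), lex)
  expect_equal(m3$field, "mesh")
  expect_error(match_entities("x", character(0), character(0), lex[0, ]),
               "non-empty")
})

test_that("corpus assembly keeps only documents mentioning an entity", {
  recs <- tibble::tibble(
    doc_id = as.character(1:5),
    title = c("brca1 study", "nothing here", "malady7 cohort",
              "brca1 and malady7", "unrelated text"),
    abstract = c("BRCA1 drives neoplasms.", "Plain text. No entities.",
                 "", "Shared doc.", ""),
    mesh = list(character(0), character(0), "anemia", character(0),
                character(0)))
  genes <- tibble::tibble(entity_id = "g1", name = "brca1")
  dis <- tibble::tibble(entity_id = "d1", name = "malady7")
  corp <- build_corpus(recs, genes, dis)
  expect_equal(nrow(corp$documents), 3L) # 2 of 5 mention no entity
  # doc 4 mentions both entities -> appears under both index entries
  expect_true(all(c("g1", "d1") %in%
                    corp$index$entity_id[corp$index$doc_id == "4"]))
  # determinism: two passes identical
  expect_identical(corp, build_corpus(recs, genes, dis))
  # empty lexicons -> empty corpus
  empty <- build_corpus(recs, genes[0, ], dis[0, ])
  expect_equal(nrow(empty$documents), 0L)
  # filtering never increases size; all-covering lexicons keep everything
  covering <- tibble::tibble(entity_id = "gX", name = c("study", "here",
                                                        "cohort", "and",
                                                        "text"))
  all_kept <- build_corpus(recs, covering, dis)
  expect_equal(nrow(all_kept$documents), 5L)
  expect_lte(nrow(corp$documents), nrow(recs))
  expect_error(build_corpus(recs, genes, genes), "share entity id")
})

test_that("lexicon files parse synonyms and reject duplicate ids", {
  path <- withr::local_tempfile(lines = c("# lex", "g1\tBRCA1|brca-1",
                                          "g2\ttp53"))
  lex <- read_lexicon(path)
  expect_equal(nrow(lex), 3L)
  expect_setequal(lex$name[lex$entity_id == "g1"], c("brca1", "brca-1"))
  dup <- withr::local_tempfile(lines = c("g1\ta", "g1\tb"))
  expect_error(read_lexicon(dup), "duplicate")
})
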