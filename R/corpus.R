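#' Read a literature corpus
#'
#' Reads MEDLINE/PubMed-style records from either PubMed XML
#' (`PubmedArticleSet` / `PubmedArticle` / `MedlineCitation`: `PMID`,
#' `ArticleTitle`, `Abstract/AbstractText`, `MeshHeadingList/DescriptorName`)
#' or a JSONL fallback with one object per line carrying keys `id`, `title`,
#' `abstract` and `mesh` (list of strings).
#'
#' Records missing an abstract are kept with an empty abstract (titles and
#' MeSH terms still carry signal). A duplicated identifier keeps the first
#' record and skips later ones with a warning.
#'
#' @param path Path to the corpus file.
#' @param format `"jsonl"` or `"medline_xml"`.
#' @return A tibble with columns `doc_id`, `title`, `abstract` and `mesh`
#'   (list-column of character vectors).
#' @export
read_corpus <- function(path, format = c("jsonl", "medline_xml")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- readr::read_lines(path)
    lines <- lines[nzchar(trimws(lines))]
    rows <- purrr::imap(lines, function(line, i) {
      rec <- tryCatch(jsonlite::fromJSON(line, simplifyVector = TRUE),
                      error = function(e) {
                        abort(sprintf("malformed corpus record %d: %s",
                                      i, conditionMessage(e)))
                      })
      if (is.null(rec$id) || is.null(rec$title)) {
        abort(sprintf("malformed corpus record %d: needs `id` and `title`", i))
      }
      tibble(doc_id = as.character(rec$id),
             title = as.character(rec$title),
             abstract = as.character(rec$abstract %||% ""),
             mesh = list(as.character(unlist(rec$mesh))))
    })
    recs <- dplyr::bind_rows(rows)
  } else {
    doc <- xml2::read_xml(path)
    arts <- xml2::xml_find_all(doc, ".//PubmedArticle | .//MedlineCitation[not(ancestor::PubmedArticle)]")
    rows <- purrr::imap(arts, function(art, i) {
      pmid <- xml2::xml_find_first(art, ".//PMID")
      title <- xml2::xml_find_first(art, ".//ArticleTitle")
      if (inherits(pmid, "xml_missing") || inherits(title, "xml_missing")) {
        abort(sprintf("malformed article record %d: missing PMID or ArticleTitle", i))
      }
      abs_nodes <- xml2::xml_find_all(art, ".//Abstract/AbstractText")
      mesh <- xml2::xml_text(
        xml2::xml_find_all(art, ".//MeshHeadingList/MeshHeading/DescriptorName"))
      tibble(doc_id = xml2::xml_text(pmid),
             title = xml2::xml_text(title),
             abstract = paste(xml2::xml_text(abs_nodes), collapse = " "),
             mesh = list(as.character(mesh)))
    })
    recs <- dplyr::bind_rows(rows)
  }
  if (nrow(recs) == 0L) {
    return(tibble(doc_id = character(0), title = character(0),
                  abstract = character(0), mesh = list()))
  }
  dup <- duplicated(recs$doc_id)
  if (any(dup)) {
    warn(sprintf("skipped %d record(s) with duplicate id: %s", sum(dup),
                 paste(unique(recs$doc_id[dup]), collapse = ", ")))
    recs <- recs[!dup, ]
  }
  n_noabs <- sum(!nzchar(trimws(recs$abstract)))
  if (n_noabs > 0L) {
    inform(sprintf("%d record(s) have no abstract; kept with empty sentence list",
                   n_noabs))
  }
  recs
}

# Abbreviations that never end a sentence (compared after stripping dots).
.sentence_abbrev <- c("e", "i", "eg", "ie", "vs", "al", "et", "fig", "figs",
                      "dr", "mr", "mrs", "ms", "no", "st", "etc", "ca", "cf",
                      "sp", "spp", "approx")

#' Split an abstract into sentences
#'
#' Deterministic rule-based splitter: a sentence boundary is terminal
#' punctuation (`.?!`) followed by whitespace and an uppercase letter or
#' digit, unless the preceding word is a single letter or a common
#' abbreviation (e.g. "E." in species names, "et al.", "Fig."). Whitespace is
#' normalized first; the concatenation of the returned sentences covers the
#' input text.
#'
#' @param text A single string (may be empty).
#' @return Character vector of non-empty sentences (empty input gives
#'   `character(0)`).
#' @export
#' @examples
#' split_sentences("A result. Another result.")
#' split_sentences("E. coli causes disease.")
split_sentences <- function(text) {
  text <- gsub("\\s+", " ", trimws(paste(text %||% "", collapse = " ")))
  if (!nzchar(text)) {
    return(character(0))
  }
  m <- gregexpr("[.?!]+ (?=[A-Z0-9])", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(text)
  }
  lens <- attr(m, "match.length")
  cuts <- integer(0)
  for (j in seq_along(m)) {
    before <- substr(text, 1L, m[j] - 1L)
    word <- tolower(gsub("[^A-Za-z0-9]", "", sub(".*\\s", "", before)))
    if (nchar(word) == 1L || word %in% .sentence_abbrev) next
    cuts <- c(cuts, j)
  }
  if (length(cuts) == 0L) {
    return(text)
  }
  starts <- c(1L, m[cuts] + lens[cuts])
  ends <- c(m[cuts] + lens[cuts] - 2L, nchar(text))
  sents <- substring(text, starts, ends)
  sents <- trimws(sents)
  sents[nzchar(sents)]
}

# Build a matching index over a set of normalized phrases. Phrases are
# canonicalized to space-joined alphanumeric tokens; `by_len[[L]]` holds all
# canonical forms of token-length L.
phrase_index <- function(phrases) {
  phrases <- unique(normalize_keyword(phrases))
  toks <- strsplit(gsub("[^a-z0-9]+", " ", phrases), " ", fixed = TRUE)
  toks <- purrr::map(toks, ~ .x[nzchar(.x)])
  keep <- lengths(toks) > 0L
  toks <- toks[keep]
  phrases <- phrases[keep]
  canon <- purrr::map_chr(toks, paste, collapse = " ")
  # first phrase wins on canonical-form collision
  first <- !duplicated(canon)
  canon <- canon[first]
  phrases <- phrases[first]
  len <- lengths(strsplit(canon, " ", fixed = TRUE))
  max_len <- if (length(len) > 0L) max(len) else 0L
  by_len <- purrr::map(seq_len(max_len), ~ canon[len == .x])
  list(by_len = by_len, max_len = max_len,
       phrase_of = stats::setNames(phrases, canon))
}

# Count non-overlapping, longest-match-first occurrences of indexed phrases
# in a token vector. Returns a named integer vector keyed by original phrase.
match_tokens <- function(tokens, idx) {
  n <- length(tokens)
  if (n == 0L || idx$max_len == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  if (idx$max_len == 1L) {
    hit <- tokens[tokens %in% idx$by_len[[1]]]
    if (length(hit) == 0L) {
      return(stats::setNames(integer(0), character(0)))
    }
    tab <- table(hit)
    return(stats::setNames(as.integer(tab), idx$phrase_of[names(tab)]))
  }
  counts <- new.env(parent = emptyenv())
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (L in seq.int(min(idx$max_len, n - i + 1L), 1L)) {
      cand <- paste(tokens[i:(i + L - 1L)], collapse = " ")
      if (cand %in% idx$by_len[[L]]) {
        cur <- counts[[cand]]
        counts[[cand]] <- if (is.null(cur)) 1L else cur + 1L
        i <- i + L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  keys <- ls(counts)
  stats::setNames(vapply(keys, function(k) counts[[k]], integer(1)),
                  idx$phrase_of[keys])
}

#' Count dictionary keywords in a text
#'
#' Case-insensitive, token-boundary matching: the text is tokenized on
#' non-alphanumeric characters and dictionary keywords are matched as
#' contiguous token runs, longest match first, non-overlapping (after a match
#' the scan continues past it).
#'
#' @param text A single string.
#' @param dict A `mesh_dict` tibble, or a character vector of keywords.
#' @return A tibble with columns `keyword`, `count` (only matched keywords).
#' @export
#' @examples
#' match_keywords("Lung neoplasms and neoplasms", c("neoplasms", "lung neoplasms"))
match_keywords <- function(text, dict) {
  kws <- if (is.data.frame(dict)) unique(dict$keyword) else dict
  idx <- phrase_index(kws)
  hits <- match_tokens(tokenize(text), idx)
  tibble(keyword = names(hits), count = as.integer(hits)) %>%
    dplyr::arrange(.data$keyword)
}

#' Read an entity lexicon
#'
#' Tab-separated, one entity per line: `entity_id<TAB>name[|name...]`.
#' Comment lines start with `#`. Names are case-normalized; duplicate
#' entity ids or empty names are errors.
#'
#' @param path Path to the lexicon TSV.
#' @return A tibble with columns `entity_id`, `name` (one row per surface
#'   name).
#' @export
read_lexicon <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  rows <- purrr::imap(lines, function(line, i) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      abort(sprintf("malformed lexicon line %d: expected entity_id<TAB>names", i))
    }
    names <- normalize_keyword(strsplit(parts[2], "|", fixed = TRUE)[[1]])
    if (any(!nzchar(names))) {
      abort(sprintf("lexicon line %d has an empty name", i))
    }
    tibble(entity_id = trimws(parts[1]), name = unique(names))
  })
  lex <- dplyr::bind_rows(rows)
  if (nrow(lex) == 0L) {
    return(tibble(entity_id = character(0), name = character(0)))
  }
  per_line_ids <- purrr::map_chr(rows, ~ .x$entity_id[1])
  if (anyDuplicated(per_line_ids)) {
    abort(sprintf("duplicate entity_id in lexicon: %s",
                  paste(unique(per_line_ids[duplicated(per_line_ids)]),
                        collapse = ", ")))
  }
  lex
}

# Entity mentions in one document. Returns tibble(entity_id, field, sentence)
# where field is "title"/"mesh"/"sentence" and sentence is NA except for
# field == "sentence". Matching rule identical to match_keywords.
match_entities_one <- function(title, sentences, mesh_terms, lex_idx,
                               name_to_id) {
  hits_in <- function(text) {
    h <- match_tokens(tokenize(text), lex_idx)
    unique(unlist(name_to_id[names(h)], use.names = FALSE))
  }
  out <- list()
  t_ids <- hits_in(title)
  if (length(t_ids) > 0L) {
    out[[length(out) + 1L]] <- tibble(entity_id = t_ids, field = "title",
                                      sentence = NA_integer_)
  }
  m_ids <- hits_in(paste(mesh_terms, collapse = " . "))
  if (length(m_ids) > 0L) {
    out[[length(out) + 1L]] <- tibble(entity_id = m_ids, field = "mesh",
                                      sentence = NA_integer_)
  }
  for (i in seq_along(sentences)) {
    s_ids <- hits_in(sentences[[i]])
    if (length(s_ids) > 0L) {
      out[[length(out) + 1L]] <- tibble(entity_id = s_ids, field = "sentence",
                                        sentence = i)
    }
  }
  if (length(out) == 0L) {
    return(tibble(entity_id = character(0), field = character(0),
                  sentence = integer(0)))
  }
  dplyr::bind_rows(out)
}

#' Locate entity mentions in a document
#'
#' Records, per entity, every field (title, MeSH terms, abstract sentence
#' `i`) containing any of the entity's surface names. Two synonyms in the
#' same field collapse to one mention (set semantics).
#'
#' @param title Document title.
#' @param sentences Character vector of abstract sentences.
#' @param mesh_terms Character vector of indexed MeSH terms.
#' @param lexicon A lexicon tibble from [read_lexicon()].
#' @return A tibble with columns `entity_id`, `field`
#'   (`"title"`/`"mesh"`/`"sentence"`) and `sentence` (1-based index, `NA`
#'   outside sentences).
#' @export
match_entities <- function(title, sentences, mesh_terms, lexicon) {
  if (nrow(lexicon) == 0L) {
    abort("`lexicon` must be non-empty")
  }
  idx <- phrase_index(lexicon$name)
  name_to_id <- split(lexicon$entity_id, normalize_keyword(lexicon$name))
  match_entities_one(title, sentences, mesh_terms, idx, name_to_id)
}

#' Assemble a corpus: sentence-split, match entities, drop unrelated records
#'
#' Splits each record's abstract into sentences, finds gene and disease
#' mentions via dictionary matching on the two lexicons, and keeps only
#' documents with at least one mention — text files unrelated to any gene or
#' disease are removed. A document may serve several entities.
#'
#' @param records Record tibble from [read_corpus()] (columns `doc_id`,
#'   `title`, `abstract`, `mesh`).
#' @param gene_lexicon,disease_lexicon Lexicon tibbles ([read_lexicon()]);
#'   their `entity_id` sets must be disjoint.
#' @return A list of class `lit_corpus` with elements `documents` (tibble:
#'   `doc_id`, `title`, `sentences` list-col, `mesh` list-col), `mentions`
#'   (tibble: `doc_id`, `entity_id`, `kind`, `field`, `sentence`) and `index`
#'   (tibble: `entity_id`, `kind`, `doc_id` — the documents mentioning each
#'   entity).
#' @export
build_corpus <- function(records, gene_lexicon, disease_lexicon) {
  clash <- intersect(gene_lexicon$entity_id, disease_lexicon$entity_id)
  if (length(clash) > 0L) {
    abort(sprintf("gene and disease lexicons share entity id(s): %s",
                  paste(clash, collapse = ", ")))
  }
  lex <- dplyr::bind_rows(
    dplyr::mutate(gene_lexicon, kind = "gene"),
    dplyr::mutate(disease_lexicon, kind = "disease"))
  empty <- list(
    documents = tibble(doc_id = character(0), title = character(0),
                       sentences = list(), mesh = list()),
    mentions = tibble(doc_id = character(0), entity_id = character(0),
                      kind = character(0), field = character(0),
                      sentence = integer(0)),
    index = tibble(entity_id = character(0), kind = character(0),
                   doc_id = character(0)))
  class(empty) <- "lit_corpus"
  if (nrow(records) == 0L || nrow(lex) == 0L) {
    return(empty)
  }
  idx <- phrase_index(lex$name)
  name_to_id <- split(lex$entity_id, normalize_keyword(lex$name))
  kind_of <- stats::setNames(lex$kind, lex$entity_id)

  sents <- purrr::map(records$abstract, split_sentences)
  ments <- purrr::pmap(
    list(records$doc_id, records$title, sents, records$mesh),
    function(id, title, ss, mesh) {
      m <- match_entities_one(title, ss, mesh, idx, name_to_id)
      if (nrow(m) > 0L) m$doc_id <- id
      m
    })
  mentions <- dplyr::bind_rows(ments)
  if (nrow(mentions) == 0L) {
    return(empty)
  }
  mentions <- mentions %>%
    dplyr::mutate(kind = unname(kind_of[.data$entity_id])) %>%
    dplyr::select("doc_id", "entity_id", "kind", "field", "sentence") %>%
    dplyr::arrange(.data$doc_id, .data$entity_id, .data$field, .data$sentence)
  keep_ids <- unique(mentions$doc_id)
  keep <- records$doc_id %in% keep_ids
  documents <- tibble(doc_id = records$doc_id[keep],
                      title = records$title[keep],
                      sentences = sents[keep],
                      mesh = records$mesh[keep])
  index <- mentions %>%
    dplyr::distinct(.data$entity_id, .data$kind, .data$doc_id) %>%
    dplyr::arrange(.data$entity_id, .data$doc_id)
  out <- list(documents = documents, mentions = mentions, index = index)
  class(out) <- "lit_corpus"
  out
}

#' @export
print.lit_corpus <- function(x, ...) {
  cat(sprintf("<lit_corpus> %d documents, %d entities mentioned, %d mentions\n",
              nrow(x$documents), length(unique(x$index$entity_id)),
              nrow(x$mentions)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
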