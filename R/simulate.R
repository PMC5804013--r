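# Run code under a fixed seed, restoring the caller's RNG state after.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration of a synthetic gene-disease literature study
#'
#' Describes the planted-signal benchmark: each gene and disease gets a
#' keyword signature drawn from deep MeSH-tree nodes; a known (gold) pair's
#' gene shares `floor(overlap * signature_size)` keywords with its disease;
#' every document about an entity carries its signature in the title,
#' abstract sentences and indexed MeSH terms, diluted by off-signature noise
#' keywords.
#'
#' @param n_genes,n_diseases Number of entities of each kind (defaults 50 and
#'   20).
#' @param n_known_pairs Number of planted gold-standard pairs (default 30);
#'   must not exceed `n_genes` (each gene takes part in at most one planted
#'   pair).
#' @param signature_size Keywords per entity signature (default 10).
#' @param overlap Fraction of a known pair's signatures that is shared, in
#'   [0, 1] (default 0.8); the shared count is `floor(overlap *
#'   signature_size)`.
#' @param docs_per_entity Documents generated per entity (default 5).
#' @param sentences_per_doc Abstract sentences per document (default 4).
#' @param keywords_per_sentence Keyword slots per sentence (default 5).
#' @param noise_rate Probability that a keyword slot draws a random
#'   vocabulary keyword instead of a signature keyword, in [0, 1) (default
#'   0.1).
#' @param co_mention_prob Probability that a sentence mentions the document's
#'   entity (default 0.8).
#' @param tree_depth,tree_branching Shape of the toy MeSH tree (defaults 6
#'   and 3; depth counts the category letter as level 1).
#' @param signature_depth_min Minimum tree depth of signature keywords
#'   (default 5, so the depth penalty does not confound signal recovery).
#' @param abstract_signal If `FALSE`, abstract sentence slots draw only
#'   random keywords — the signal lives solely in titles and MeSH terms.
#' @param n_confounders Number of shallow generic keywords appended to every
#'   document's MeSH-term list (default 0).
#' @param confounder_depth Maximum tree depth of confounder keywords
#'   (default 2).
#' @param seed Integer seed controlling every random draw.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50, n_diseases = 20, n_known_pairs = 30,
                       signature_size = 10, overlap = 0.8,
                       docs_per_entity = 5, sentences_per_doc = 4,
                       keywords_per_sentence = 5, noise_rate = 0.1,
                       co_mention_prob = 0.8, tree_depth = 6,
                       tree_branching = 3, signature_depth_min = 5,
                       abstract_signal = TRUE, n_confounders = 0,
                       confounder_depth = 2, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_diseases = as.integer(n_diseases),
              n_known_pairs = as.integer(n_known_pairs),
              signature_size = as.integer(signature_size),
              overlap = overlap,
              docs_per_entity = as.integer(docs_per_entity),
              sentences_per_doc = as.integer(sentences_per_doc),
              keywords_per_sentence = as.integer(keywords_per_sentence),
              noise_rate = noise_rate,
              co_mention_prob = co_mention_prob,
              tree_depth = as.integer(tree_depth),
              tree_branching = as.integer(tree_branching),
              signature_depth_min = as.integer(signature_depth_min),
              abstract_signal = isTRUE(abstract_signal),
              n_confounders = as.integer(n_confounders),
              confounder_depth = as.integer(confounder_depth),
              seed = as.integer(seed))
  for (f in c("n_genes", "n_diseases", "n_known_pairs", "signature_size",
              "docs_per_entity", "sentences_per_doc",
              "keywords_per_sentence")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      usage_error(sprintf("`%s` must be a positive integer", f))
    }
  }
  if (cfg$tree_depth < 2L || cfg$tree_branching < 2L) {
    usage_error("`tree_depth` and `tree_branching` must both be >= 2")
  }
  if (is.na(cfg$overlap) || cfg$overlap < 0 || cfg$overlap > 1) {
    usage_error("`overlap` must lie in [0, 1]")
  }
  if (is.na(cfg$noise_rate) || cfg$noise_rate < 0 || cfg$noise_rate >= 1) {
    usage_error("`noise_rate` must lie in [0, 1)")
  }
  if (is.na(cfg$co_mention_prob) || cfg$co_mention_prob < 0 ||
      cfg$co_mention_prob > 1) {
    usage_error("`co_mention_prob` must lie in [0, 1]")
  }
  if (cfg$n_known_pairs > cfg$n_genes * cfg$n_diseases) {
    usage_error("`n_known_pairs` cannot exceed n_genes * n_diseases")
  }
  if (cfg$n_known_pairs > cfg$n_genes) {
    usage_error("`n_known_pairs` cannot exceed `n_genes` (one planted pair per gene)")
  }
  if (cfg$n_confounders < 0L) {
    usage_error("`n_confounders` must be >= 0")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a toy MeSH tree
#'
#' A complete `tree_branching`-ary tree of keywords under each of the five
#' kept categories (A, B, C, D, F), down to `tree_depth` levels (category
#' letter = level 1). Keyword names encode their position (e.g.
#' `kwc01x02`) so fixtures are debuggable; tree numbers follow the MeSH
#' style (`C01.02`).
#'
#' @param cfg A [sim_config()].
#' @return A `mesh_dict` tibble.
#' @export
generate_tree <- function(cfg = sim_config()) {
  cats <- c("A", "B", "C", "D", "F")
  rows <- list()
  for (cat in cats) {
    paths <- list(integer(0))
    for (lvl in seq_len(cfg$tree_depth - 1L)) {
      paths <- unlist(purrr::map(paths, function(p) {
        purrr::map(seq_len(cfg$tree_branching), ~ c(p, .x))
      }), recursive = FALSE)
      segs <- purrr::map_chr(paths, ~ paste(sprintf("%02d", .x), collapse = "."))
      rows[[length(rows) + 1L]] <- tibble(
        keyword = paste0("kw", tolower(cat),
                         purrr::map_chr(paths, ~ paste(sprintf("%02d", .x),
                                                       collapse = "x"))),
        tree_number = paste0(cat, segs))
    }
  }
  dplyr::bind_rows(rows) %>%
    dplyr::mutate(category = substr(.data$tree_number, 1L, 1L),
                  depth = tree_depth(.data$tree_number)) %>%
    dplyr::arrange(.data$keyword, .data$tree_number) %>%
    new_mesh_dict()
}

#' Generate a synthetic study: corpus, lexicons, gold standard
#'
#' Draws disjoint keyword signatures for every entity from tree nodes at
#' depth `signature_depth_min` or deeper (a known pair's gene re-uses the
#' shared part of its disease's signature), then writes `docs_per_entity`
#' documents per entity: the title holds the entity name plus two signature
#' keywords, each abstract sentence fills `keywords_per_sentence` slots from
#' the signature (or, with probability `noise_rate`, from the whole
#' vocabulary) and mentions the entity with probability `co_mention_prob`,
#' and the indexed MeSH terms are three signature keywords (plus any
#' confounders). Entity names are synthetic tokens absent from the keyword
#' vocabulary. Fully reproducible given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_study`: `config`, `dictionary`
#'   (`mesh_dict`), `records` (corpus tibble as from [read_corpus()]),
#'   `gene_lexicon`, `disease_lexicon` (tibbles `entity_id`, `name`),
#'   `gold` (tibble `gene_id`, `disease_id`) and `signatures` (list keyed by
#'   entity id, for diagnostics).
#' @export
generate_study <- function(cfg = sim_config()) {
  dict <- generate_tree(cfg)
  vocab <- sort(unique(dict$keyword))
  depths <- keyword_depth(dict, "max")
  deep <- sort(depths$keyword[depths$depth >= cfg$signature_depth_min])
  gene_ids <- sprintf("g%03d", seq_len(cfg$n_genes))
  disease_ids <- sprintf("d%03d", seq_len(cfg$n_diseases))
  gene_names <- sprintf("genesym%03d", seq_len(cfg$n_genes))
  disease_names <- sprintf("malady%03d", seq_len(cfg$n_diseases))
  n_shared <- floor(cfg$overlap * cfg$signature_size)
  demand <- cfg$n_diseases * cfg$signature_size +
    cfg$n_genes * cfg$signature_size - cfg$n_known_pairs * n_shared
  if (demand > length(deep)) {
    abort(sprintf(paste0("signature demand (%d keywords) exceeds the deep ",
                         "vocabulary (%d at depth >= %d); increase ",
                         "tree_depth or tree_branching"),
                  demand, length(deep), cfg$signature_depth_min))
  }
  with_local_seed(cfg$seed, {
    pool <- sample(deep)
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    dis_sig <- stats::setNames(
      purrr::map(seq_len(cfg$n_diseases), ~ take(cfg$signature_size)),
      disease_ids)
    known_genes <- sort(sample(gene_ids, cfg$n_known_pairs))
    known_dis <- sample(disease_ids, cfg$n_known_pairs, replace = TRUE)
    gold <- tibble(gene_id = known_genes, disease_id = known_dis) %>%
      dplyr::arrange(.data$gene_id, .data$disease_id)
    pair_of <- stats::setNames(gold$disease_id, gold$gene_id)
    gene_sig <- stats::setNames(
      purrr::map(gene_ids, function(g) {
        if (g %in% names(pair_of) && n_shared > 0L) {
          shared <- sample(dis_sig[[pair_of[[g]]]], n_shared)
          c(shared, take(cfg$signature_size - n_shared))
        } else {
          take(cfg$signature_size)
        }
      }),
      gene_ids)
    confounders <- character(0)
    if (cfg$n_confounders > 0L) {
      shallow <- sort(depths$keyword[depths$depth <= cfg$confounder_depth])
      if (cfg$n_confounders > length(shallow)) {
        abort(sprintf("only %d keyword(s) at depth <= %d available for confounders",
                      length(shallow), cfg$confounder_depth))
      }
      confounders <- sample(shallow, cfg$n_confounders)
    }
    all_ids <- c(gene_ids, disease_ids)
    all_names <- stats::setNames(c(gene_names, disease_names), all_ids)
    sigs <- c(gene_sig, dis_sig)
    doc_rows <- list()
    doc_n <- 0L
    for (eid in all_ids) {
      sig <- sigs[[eid]]
      ename <- all_names[[eid]]
      for (j in seq_len(cfg$docs_per_entity)) {
        doc_n <- doc_n + 1L
        title <- paste0(ename, " and ", paste(sample(sig, 2L), collapse = " "),
                        ".")
        sents <- purrr::map_chr(seq_len(cfg$sentences_per_doc), function(s) {
          slots <- purrr::map_chr(seq_len(cfg$keywords_per_sentence),
                                  function(t) {
            if (!cfg$abstract_signal || stats::runif(1) < cfg$noise_rate) {
              sample(vocab, 1L)
            } else {
              sample(sig, 1L)
            }
          })
          subject <- if (stats::runif(1) < cfg$co_mention_prob) {
            paste("Study of", ename, "examined")
          } else {
            "Observations covered"
          }
          paste0(subject, " ", paste(slots, collapse = " "), ".")
        })
        mesh <- unique(c(sample(sig, 3L), confounders))
        doc_rows[[doc_n]] <- tibble(
          doc_id = sprintf("doc%05d", doc_n),
          title = title,
          abstract = paste(sents, collapse = " "),
          mesh = list(mesh))
      }
    }
    study <- list(
      config = cfg,
      dictionary = dict,
      records = dplyr::bind_rows(doc_rows),
      gene_lexicon = tibble(entity_id = gene_ids, name = gene_names),
      disease_lexicon = tibble(entity_id = disease_ids,
                               name = disease_names),
      gold = gold,
      signatures = sigs)
    class(study) <- "sim_study"
    study
  })
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(paste0("<sim_study> %d genes, %d diseases, %d known pairs, ",
                     "%d documents, %d dictionary keywords (seed %d)\n"),
              nrow(x$gene_lexicon), nrow(x$disease_lexicon), nrow(x$gold),
              nrow(x$records), length(unique(x$dictionary$keyword)),
              x$config$seed))
  invisible(x)
}

#' Write a generated study to disk in pipeline-native formats
#'
#' Emits exactly what the pipeline consumes: `corpus.jsonl`, `dict.tsv`
#' (tabular dictionary dialect), `genes.tsv` and `diseases.tsv` (lexicon
#' TSV), `gold.tsv`, and `manifest.json` recording the full configuration
#' including the seed.
#'
#' @param study A `sim_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lines <- purrr::pmap_chr(study$records, function(doc_id, title, abstract,
                                                   mesh) {
    jsonlite::toJSON(list(id = doc_id, title = title, abstract = abstract,
                          mesh = as.list(mesh)), auto_unbox = TRUE)
  })
  readr::write_lines(lines, file.path(dir, "corpus.jsonl"))
  write_mesh(study$dictionary, file.path(dir, "dict.tsv"))
  readr::write_lines(paste0(study$gene_lexicon$entity_id, "\t",
                            study$gene_lexicon$name),
                     file.path(dir, "genes.tsv"))
  readr::write_lines(paste0(study$disease_lexicon$entity_id, "\t",
                            study$disease_lexicon$name),
                     file.path(dir, "diseases.tsv"))
  write_gold(study$gold, file.path(dir, "gold.tsv"))
  write_manifest(file.path(dir, "manifest.json"),
                 unclass(study$config))
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Directory containing `corpus.jsonl`, `dict.tsv`, `genes.tsv`,
#'   `diseases.tsv` and `gold.tsv`.
#' @return A list with elements `dictionary`, `records`, `gene_lexicon`,
#'   `disease_lexicon`, `gold` (class `sim_study` minus `signatures`).
#' @export
read_study <- function(dir) {
  needed <- c("corpus.jsonl", "dict.tsv", "genes.tsv", "diseases.tsv",
              "gold.tsv")
  missing <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing) > 0L) {
    abort(sprintf("study directory %s is missing: %s", dir,
                  paste(missing, collapse = ", ")))
  }
  study <- list(
    config = NULL,
    dictionary = read_mesh(file.path(dir, "dict.tsv"), "tabular"),
    records = read_corpus(file.path(dir, "corpus.jsonl"), "jsonl"),
    gene_lexicon = read_lexicon(file.path(dir, "genes.tsv")),
    disease_lexicon = read_lexicon(file.path(dir, "diseases.tsv")),
    gold = read_gold(file.path(dir, "gold.tsv")))
  manifest <- file.path(dir, "manifest.json")
  if (file.exists(manifest)) {
    study$config <- jsonlite::fromJSON(manifest)
  }
  class(study) <- "sim_study"
  study
}
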