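#' Parse MeSH descriptors into a tree-position dictionary
#'
#' Reads MeSH descriptors from either the official descriptor XML
#' (`DescriptorRecordSet` / `DescriptorRecord` / `DescriptorName` /
#' `TreeNumberList`) or a simplified tabular dialect
#' (`keyword<TAB>treenum[;treenum...]`, `#` comments, UTF-8) and returns one
#' row per (keyword, tree position).
#'
#' Depth counts the category letter as level 1, so a tree number with `s`
#' dot-separated segments sits at depth `s + 1`; `"C04.588"` has depth 3.
#' Keywords are case-normalized ([normalize_keyword()]). Descriptors with no
#' tree number are skipped with a warning; a malformed record raises an error
#' naming its position.
#'
#' @param path Path to the descriptor file.
#' @param format `"xml"` (official descriptor XML) or `"tabular"`.
#' @return A tibble with class `mesh_dict` and columns `keyword`,
#'   `tree_number`, `category` (first letter of the tree number) and `depth`.
#' @seealso [filter_categories()], [keyword_depth()], [pwk()]
#' @export
read_mesh <- function(path, format = c("tabular", "xml")) {
  format <- match.arg(format)
  if (format == "xml") {
    doc <- xml2::read_xml(path)
    recs <- xml2::xml_find_all(doc, ".//DescriptorRecord")
    rows <- purrr::imap(recs, function(rec, i) {
      name <- xml2::xml_find_first(rec, "./DescriptorName/String")
      if (inherits(name, "xml_missing")) {
        abort(sprintf("malformed descriptor record %d: missing DescriptorName", i))
      }
      tns <- xml2::xml_text(
        xml2::xml_find_all(rec, "./TreeNumberList/TreeNumber"))
      tibble(keyword = normalize_keyword(xml2::xml_text(name)),
             tree_number = as.character(tns))
    })
    dict <- dplyr::bind_rows(rows)
    skipped <- purrr::map_lgl(rows, ~ nrow(.x) == 0L)
    if (any(skipped)) {
      warn(sprintf("skipped %d descriptor(s) with no tree number", sum(skipped)))
    }
  } else {
    lines <- readr::read_lines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    rows <- purrr::imap(lines, function(line, i) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2L || !nzchar(trimws(parts[1]))) {
        abort(sprintf("malformed dictionary record %d: expected keyword<TAB>treenums", i))
      }
      tns <- trimws(strsplit(parts[2], ";", fixed = TRUE)[[1]])
      tns <- tns[nzchar(tns)]
      if (length(tns) == 0L) {
        warn(sprintf("record %d ('%s') has no tree number; skipped", i, parts[1]))
        return(NULL)
      }
      tibble(keyword = normalize_keyword(parts[1]), tree_number = tns)
    })
    dict <- dplyr::bind_rows(rows)
  }
  if (nrow(dict) == 0L) {
    dict <- tibble(keyword = character(0), tree_number = character(0))
  }
  dict %>%
    dplyr::distinct(.data$keyword, .data$tree_number) %>%
    dplyr::mutate(category = substr(.data$tree_number, 1L, 1L),
                  depth = tree_depth(.data$tree_number)) %>%
    dplyr::arrange(.data$keyword, .data$tree_number) %>%
    new_mesh_dict()
}

new_mesh_dict <- function(x) {
  class(x) <- unique(c("mesh_dict", class(x)))
  x
}

# Depth of a dot-separated tree number: segments + 1 (category letter = 1).
tree_depth <- function(tree_number) {
  lengths(strsplit(tree_number, ".", fixed = TRUE)) + 1L
}

#' Write a dictionary in the tabular dialect
#'
#' Inverse of `read_mesh(format = "tabular")`: one line per keyword with its
#' tree numbers semicolon-separated, sorted, so that parse/serialize
#' round-trips bit-identically.
#'
#' @param dict A `mesh_dict` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(dict, path) {
  out <- dict %>%
    dplyr::group_by(.data$keyword) %>%
    dplyr::summarise(tns = paste(sort(.data$tree_number), collapse = ";"),
                     .groups = "drop") %>%
    dplyr::arrange(.data$keyword)
  readr::write_lines(paste0(out$keyword, "\t", out$tns), path)
  invisible(path)
}

#' Restrict a dictionary to a set of MeSH categories
#'
#' Drops tree positions outside `keep` and then keywords left with no
#' position. The default `keep` is the five categories used for
#' disease-oriented mining: anatomy (A), organisms (B), diseases (C),
#' chemicals and drugs (D), and psychiatry and psychology (F).
#'
#' @param dict A `mesh_dict` tibble from [read_mesh()].
#' @param keep Character vector of single-letter category codes.
#' @return The filtered `mesh_dict`.
#' @export
filter_categories <- function(dict, keep = c("A", "B", "C", "D", "F")) {
  if (length(keep) == 0L) {
    abort("`keep` must name at least one MeSH category")
  }
  valid <- LETTERS
  bad <- setdiff(keep, valid)
  if (length(bad) > 0L) {
    abort(sprintf("unknown category code(s) %s; valid codes are single letters A-Z",
                  paste(shQuote(bad), collapse = ", ")))
  }
  dict %>%
    dplyr::filter(.data$category %in% keep) %>%
    new_mesh_dict()
}

#' Aggregate per-position depths into one depth per keyword
#'
#' MeSH is polyhierarchical: one descriptor can sit in several branches at
#' different depths, and the depth penalty needs a single value per keyword.
#' `rule = "max"` (default) takes the deepest (most specific) placement;
#' `"min"` the shallowest.
#'
#' @param dict A `mesh_dict` tibble.
#' @param rule `"max"` or `"min"`.
#' @return A tibble with columns `keyword`, `depth`.
#' @export
keyword_depth <- function(dict, rule = c("max", "min")) {
  rule <- match.arg(rule)
  if (nrow(dict) == 0L) {
    abort("cannot compute keyword depth of an empty dictionary")
  }
  agg <- if (rule == "max") max else min
  dict %>%
    dplyr::group_by(.data$keyword) %>%
    dplyr::summarise(depth = as.integer(agg(.data$depth)), .groups = "drop") %>%
    dplyr::arrange(.data$keyword)
}

#' Depth penalty for keywords near the MeSH root
#'
#' Generic descriptors close to the category root (e.g. "family") carry
#' little disease specificity yet can still score a high inverse-frequency
#' weight. The penalty halves a keyword's weight for every level it sits
#' above depth 5:
#' \deqn{PWK(T) = 2^{T-5} \ (T < 5); \quad 1 \ (T \ge 5)}
#'
#' @param depth Integer vector of keyword depths (>= 1).
#' @return Numeric vector of penalties in (0, 1].
#' @export
#' @examples
#' pwk(1:6) # 0.0625 0.125 0.25 0.5 1 1
pwk <- function(depth) {
  if (length(depth) == 0L) {
    return(numeric(0))
  }
  if (any(!is.finite(depth)) || any(depth < 1)) {
    abort("`depth` must be >= 1")
  }
  ifelse(depth < 5, 2^(depth - 5), 1)
}
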