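# Triage view payloads: the query-result heatmap (documents x query words),
# the per-document term-distribution matrix (counts in title / journal name /
# MeSH terms / abstract text), and the term-encoded abstract (character
# spans of query-word occurrences). Column color indices are assigned once,
# in query-word order, and shared by every view.

#' Query-result heatmap matrix
#'
#' One row per ranked document, one column per query word. Cell counts pool
#' raw occurrences over the four indexed fields; cell saturation is the
#' count divided by the column maximum over the displayed rows, so the most
#' frequent cell of each non-empty column has saturation 1 and a count of 0
#' always maps to saturation 0 (a white cell means no occurrence).
#'
#' @param index A `corpus_index`.
#' @param hits data.frame from [search_index()] (rows define heatmap order).
#' @param query_words Pooled distinct query words of all selected
#'   phenotypes; their order fixes the column color indices reused by
#'   [term_distribution()] and [encode_abstract()].
#' @return Object of class `heatmap_matrix`: list with `pmids`, `words`,
#'   `color_index`, `counts` (documents x words matrix) and `saturation`.
#'   Empty hits give a 0-row matrix (valid).
#' @export
build_heatmap <- function(index, hits, query_words) {
  stopifnot(inherits(index, "corpus_index"))
  words <- unique(tokenize(query_words))
  pmids <- as.integer(hits$pmid)
  counts <- matrix(0, nrow = length(pmids), ncol = length(words),
                   dimnames = list(as.character(pmids), words))
  for (i in seq_along(pmids)) {
    v <- index$doc_vectors[[as.character(pmids[i])]]
    hit <- words %in% names(v)
    counts[i, hit] <- v[words[hit]]
  }
  col_max <- if (nrow(counts)) apply(counts, 2, max) else
    stats::setNames(numeric(length(words)), words)
  saturation <- counts
  for (j in seq_along(words)) {
    saturation[, j] <- if (col_max[j] > 0) counts[, j] / col_max[j] else 0
  }
  structure(list(pmids = pmids, words = words,
                 color_index = seq_along(words),
                 counts = counts, saturation = saturation),
            class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat(sprintf("<heatmap_matrix> %d documents x %d query words\n",
              length(x$pmids), length(x$words)))
  if (length(x$words)) {
    cat("  columns:", paste(sprintf("%s[%d]", x$words, x$color_index),
                            collapse = " "), "\n")
  }
  invisible(x)
}

#' Term-distribution matrix for one document
#'
#' Counts each query word in the four metadata places of the citation --
#' title, journal name, MeSH terms (token occurrences across all headings)
#' and abstract text -- using the shared tokenizer. A word appearing only
#' in the journal name is likely less relevant than one appearing five
#' times in the abstract; this matrix is what makes that visible.
#'
#' @param citation A `citation`.
#' @param query_words Query words (same order as the heatmap columns).
#' @return Object of class `term_distribution`: list with `words`,
#'   `color_index`, `counts` (4 x n_words matrix with rows title, journal,
#'   mesh, abstract) and `metadata` (title, journal, year, mesh_terms).
#' @export
term_distribution <- function(citation, query_words) {
  stopifnot(inherits(citation, "citation_record"))
  words <- unique(tokenize(query_words))
  ft <- field_tokens(citation)
  counts <- matrix(0, nrow = 4, ncol = length(words),
                   dimnames = list(index_fields(), words))
  for (f in index_fields()) {
    for (w in words) counts[f, w] <- sum(ft[[f]] == w)
  }
  structure(list(words = words, color_index = seq_along(words),
                 counts = counts,
                 metadata = list(title = citation$title,
                                 journal = citation$journal,
                                 year = citation$year,
                                 mesh_terms = citation$mesh_terms)),
            class = "term_distribution")
}

#' @export
print.term_distribution <- function(x, ...) {
  cat("<term_distribution>", x$metadata$title, "\n")
  print(x$counts)
  invisible(x)
}

#' Character spans of query words in an abstract
#'
#' Finds every token-boundary, case-insensitive occurrence of each query
#' word in the abstract text, for color-coded rendering. Spans are 1-based,
#' inclusive, non-overlapping and sorted by start; `word_index` ties each
#' span to the heatmap column color of the matched word.
#'
#' @param citation A `citation`.
#' @param query_words Query words (same order as the heatmap columns).
#' @return data.frame with columns `word_index`, `word`, `start`, `end`.
#'   Empty abstract gives zero rows.
#' @export
encode_abstract <- function(citation, query_words) {
  stopifnot(inherits(citation, "citation_record"))
  words <- unique(tokenize(query_words))
  empty <- data.frame(word_index = integer(0), word = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(citation$abstract) || !length(words)) return(empty)
  rows <- list()
  for (j in seq_along(words)) {
    pat <- paste0("(?<![a-z0-9])", words[j], "(?![a-z0-9])")
    m <- gregexpr(pat, citation$abstract, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    rows[[length(rows) + 1L]] <- data.frame(
      word_index = j, word = words[j], start = as.integer(m),
      end = as.integer(m) + len - 1L, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
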