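# Sensitivity-encoded query selectors: for each selected phenotype name,
# every combination of its (stopword-filtered) words is searched and the
# match counts are reported, so the user can see how many additional
# articles a relaxed query would reach.

#' Query words of a phenotype name
#'
#' Tokenizes the name, removes stopwords and deduplicates preserving first
#' occurrence. "congenital fibrosis of extraocular muscles" therefore
#' contributes four words, not five.
#'
#' @param name Phenotype name.
#' @param stopwords Stopword list; defaults to [default_stopwords()].
#' @return Character vector of distinct query words.
#' @examples
#' phenotype_words("congenital fibrosis of extraocular muscles")
#' @export
phenotype_words <- function(name, stopwords = default_stopwords()) {
  assert_scalar_string(name, "name")
  toks <- tokenize(name)
  words <- unique(toks[!toks %in% stopwords])
  if (!length(words)) {
    stop("phenotype name reduces to zero query words: ", name, call. = FALSE)
  }
  words
}

#' A multi-phenotype selection
#'
#' Pools the distinct query words of every selected phenotype (used for
#' heatmap columns), while keeping the per-phenotype word lists that the
#' combination expansion operates on.
#'
#' @param phenotypes Character vector of phenotype names, optionally named
#'   by term id.
#' @param stopwords Stopword list.
#' @return Object of class `phenotype_selection` with components
#'   `selections` (data.frame `term_id`, `name`), `per_phenotype` (list of
#'   word vectors) and `words` (pooled distinct words in first-seen order).
#' @export
phenotype_selection <- function(phenotypes,
                                stopwords = default_stopwords()) {
  if (!is.character(phenotypes) || !length(phenotypes)) {
    stop("`phenotypes` must be a non-empty character vector", call. = FALSE)
  }
  ids <- names(phenotypes)
  if (is.null(ids)) ids <- rep(NA_character_, length(phenotypes))
  ids[!is.na(ids) & ids == ""] <- NA_character_
  per <- lapply(phenotypes, phenotype_words, stopwords = stopwords)
  structure(list(
    selections = data.frame(term_id = ids, name = unname(phenotypes),
                            stringsAsFactors = FALSE),
    per_phenotype = per,
    words = unique(unlist(per, use.names = FALSE))),
    class = "phenotype_selection")
}

#' @export
print.phenotype_selection <- function(x, ...) {
  cat(sprintf("<phenotype_selection> %d phenotype(s), %d pooled words\n",
              nrow(x$selections), length(x$words)))
  for (i in seq_len(nrow(x$selections))) {
    cat(sprintf("  %s: %s\n", x$selections$name[i],
                paste(x$per_phenotype[[i]], collapse = " ")))
  }
  invisible(x)
}

#' Enumerate all non-empty word combinations
#'
#' Generates all `2^n - 1` non-empty subsets of `words`, ordered by subset
#' size descending (the full phrase first) and, within a size, by the
#' original word order of the constituents.
#'
#' @param words Character vector of distinct words.
#' @param limit Maximum allowed word count (guards the exponential blow-up).
#' @return List of character vectors.
#' @examples
#' enumerate_combinations(c("progressive", "external", "ophthalmoplegia"))
#' @export
enumerate_combinations <- function(words,
                                   limit = triage_config()$combo_word_limit) {
  if (!is.character(words) || !length(words) || anyDuplicated(words)) {
    stop("`words` must be a non-empty vector of distinct words",
         call. = FALSE)
  }
  n <- length(words)
  if (n > limit) {
    stop(sprintf(paste0(
      "%d words exceed the combination limit of %d; expand each phenotype ",
      "separately or raise `combo_word_limit`"), n, limit), call. = FALSE)
  }
  out <- list()
  for (k in n:1) {
    idx <- utils::combn(n, k, simplify = FALSE)  # already lexicographic
    out <- c(out, lapply(idx, function(i) words[i]))
  }
  out
}

#' Sensitivity-encoded expansion table
#'
#' For every phenotype in the selection, searches the index with every
#' combination of that phenotype's words (conjunctive, uncapped) and
#' reports the match count, the number of **additional** articles relative
#' to the phenotype's full word set, and a bar fraction (count normalized
#' to the maximum count over all emitted rows) for visual encoding.
#'
#' @param index A `corpus_index`.
#' @param selection A `phenotype_selection` (or character vector of names).
#' @param config A [triage_config()] (stopword list and combination limit).
#' @return data.frame with columns `phenotype`, `combo` (words joined by
#'   `"+"`), `n_words`, `count`, `additional`, `bar_fraction`.
#' @export
expansion_table <- function(index, selection, config = triage_config()) {
  stopifnot(inherits(index, "corpus_index"))
  if (is.character(selection)) {
    selection <- phenotype_selection(selection, stopwords = config$stopwords)
  }
  stopifnot(inherits(selection, "phenotype_selection"))
  rows <- list()
  for (i in seq_len(nrow(selection$selections))) {
    words <- selection$per_phenotype[[i]]
    combos <- enumerate_combinations(words, limit = config$combo_word_limit)
    full_count <- count_matches(index, words)
    for (combo in combos) {
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = selection$selections$name[i],
        combo = paste(combo, collapse = "+"),
        n_words = length(combo),
        count = count_matches(index, combo),
        stringsAsFactors = FALSE)
    }
    n_new <- length(combos)
    idx_new <- (length(rows) - n_new + 1L):length(rows)
    for (j in idx_new) rows[[j]]$additional <- rows[[j]]$count - full_count
  }
  out <- do.call(rbind, rows)
  max_count <- max(out$count, 0)
  out$bar_fraction <- if (max_count > 0) out$count / max_count else 0
  rownames(out) <- NULL
  out
}
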