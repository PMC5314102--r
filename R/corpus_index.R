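# Field-aware inverted index with tf-idf weighting and vector-space cosine
# ranking, built from scratch over MEDLINE-style citations.
#
# Weighting (Lucene-style classic VSM):
#   document term weight  w_d(t) = sqrt(tf_d(t)) * idf(t)
#   query term weight     w_q(t) = idf(t)
#   idf(t)                = 1 + ln(N / (1 + df(t)))
#   score(q, d)           = sum_t w_d(t) w_q(t) / (|w_d| * |w_q|)
# where tf_d(t) pools raw counts over the four indexed fields (title,
# journal, mesh, abstract). df counts document-level presence in any field.

index_fields <- function() c("title", "journal", "mesh", "abstract")

field_tokens <- function(citation) {
  list(title = tokenize(citation$title),
       journal = tokenize(citation$journal),
       mesh = tokenize(citation$mesh_terms),
       abstract = tokenize(citation$abstract))
}

#' Build a corpus index over citations
#'
#' Tokenizes the title, journal name, MeSH headings and abstract of each
#' citation with the shared [tokenize()] normalizer and records per-field
#' raw counts, document frequencies (document-level: a token present in
#' several fields of one document counts once) and per-document vector norms
#' under the tf-idf weighting used by [score_document()].
#'
#' @param citations List of `citation` records with unique PMIDs.
#' @return Object of class `corpus_index` with components `N`, `df` (named
#'   integer), `token_docs` (token -> character vector of PMIDs),
#'   `field_counts` (pmid -> field -> named token counts), `doc_vectors`
#'   (pmid -> pooled named token counts), `doc_norms` (named numeric) and
#'   `citations` (pmid -> `citation`).
#' @export
build_corpus_index <- function(citations) {
  pmids <- vapply(citations, `[[`, integer(1), "pmid")
  if (anyDuplicated(pmids)) stop("duplicate PMIDs in corpus", call. = FALSE)
  N <- length(citations)
  key <- as.character(pmids)

  field_counts <- vector("list", N)
  doc_vectors <- vector("list", N)
  df_env <- new.env(parent = emptyenv())
  docs_env <- new.env(parent = emptyenv())

  for (i in seq_len(N)) {
    ft <- field_tokens(citations[[i]])
    fc <- lapply(ft, function(toks) {
      if (!length(toks)) return(numeric(0))
      tab <- table(toks)
      stats::setNames(as.numeric(tab), names(tab))
    })
    field_counts[[i]] <- fc
    all_toks <- unlist(ft, use.names = FALSE)
    pooled <- if (length(all_toks)) {
      tab <- table(all_toks)
      stats::setNames(as.numeric(tab), names(tab))
    } else numeric(0)
    doc_vectors[[i]] <- pooled
    for (tok in names(pooled)) {
      df_env[[tok]] <- (df_env[[tok]] %||% 0L) + 1L
      docs_env[[tok]] <- c(docs_env[[tok]], key[i])
    }
  }
  names(field_counts) <- key
  names(doc_vectors) <- key

  toks <- ls(df_env)
  df <- stats::setNames(vapply(toks, function(t) df_env[[t]], integer(1)),
                        toks)
  token_docs <- stats::setNames(lapply(toks, function(t) docs_env[[t]]),
                                toks)

  doc_norms <- vapply(doc_vectors, function(v) {
    if (!length(v)) return(0)
    w <- sqrt(v) * idf_weight(N, df[names(v)])
    sqrt(sum(w^2))
  }, numeric(1))

  structure(list(N = N, df = df, token_docs = token_docs,
                 field_counts = field_counts, doc_vectors = doc_vectors,
                 doc_norms = doc_norms,
                 citations = stats::setNames(citations, key),
                 format_version = 1L),
            class = "corpus_index")
}

idf_weight <- function(N, df) 1 + log(N / (1 + df))

#' Per-field posting counts of a token
#'
#' @param index A `corpus_index`.
#' @param token A normalized token.
#' @return data.frame with columns `pmid`, `field`, `count` (rows with
#'   count >= 1 only).
#' @export
index_postings <- function(index, token) {
  stopifnot(inherits(index, "corpus_index"))
  docs <- index$token_docs[[token]]
  rows <- list()
  for (d in docs) {
    for (f in index_fields()) {
      cnt <- index$field_counts[[d]][[f]][token]
      if (!is.na(cnt) && cnt >= 1) {
        rows[[length(rows) + 1L]] <- data.frame(
          pmid = as.integer(d), field = f, count = as.numeric(cnt),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(pmid = integer(0), field = character(0),
                      count = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Cosine similarity of a query to one document
#'
#' Duplicate query tokens collapse to one dimension (the query vector has a
#' single idf-weighted coordinate per distinct token), so scores are
#' invariant to token order and repetition.
#'
#' @param index A `corpus_index`.
#' @param query_tokens Character vector of (raw or normalized) query words.
#' @param pmid A PMID present in the index.
#' @return The vector-space cosine score; 0 when no query token occurs in
#'   the document.
#' @export
score_document <- function(index, query_tokens, pmid) {
  stopifnot(inherits(index, "corpus_index"))
  key <- as.character(pmid)
  if (!key %in% names(index$doc_vectors)) {
    stop("unknown pmid: ", pmid, call. = FALSE)
  }
  q <- unique(tokenize(query_tokens))
  if (!length(q)) return(0)
  df_q <- ifelse(is.na(index$df[q]), 0L, index$df[q])
  idf <- idf_weight(index$N, df_q)
  q_norm <- sqrt(sum(idf^2))
  v <- index$doc_vectors[[key]]
  present <- q %in% names(v)
  if (!any(present) || index$doc_norms[[key]] == 0 || q_norm == 0) return(0)
  dot <- sum(sqrt(v[q[present]]) * idf[present] * idf[present])
  unname(dot / (index$doc_norms[[key]] * q_norm))
}

conjunctive_candidates <- function(index, q, conjunctive) {
  sets <- lapply(q, function(t) index$token_docs[[t]] %||% character(0))
  if (conjunctive) Reduce(intersect, sets) else unique(unlist(sets))
}

#' Rank documents for a query
#'
#' Candidates are the documents containing **all** query tokens
#' (`conjunctive = TRUE`, the triage default) or at least one
#' (`conjunctive = FALSE`), scored by [score_document()] and sorted by score
#' descending with ties broken by PMID descending (newer citations first).
#' The result is truncated to `cap` rows; `cap = Inf` returns everything.
#'
#' @param index A `corpus_index`.
#' @param query_tokens Non-empty character vector of query words.
#' @param conjunctive Require all tokens (`TRUE`) or any (`FALSE`).
#' @param cap Maximum hits returned (default the 250-document display cap).
#' @return data.frame with columns `pmid`, `score`, `rank` (rank contiguous
#'   from 1).
#' @export
search_index <- function(index, query_tokens, conjunctive = TRUE,
                         cap = triage_config()$heatmap_cap) {
  stopifnot(inherits(index, "corpus_index"))
  q <- unique(tokenize(query_tokens))
  if (!length(q)) stop("empty query", call. = FALSE)
  assert_count(cap, "cap")
  cand <- conjunctive_candidates(index, q, conjunctive)
  if (!length(cand)) {
    return(data.frame(pmid = integer(0), score = numeric(0),
                      rank = integer(0)))
  }
  scores <- vapply(cand, function(d) score_document(index, q, d), numeric(1))
  pm <- as.integer(cand)
  ord <- order(-scores, -pm)
  keep <- utils::head(ord, cap)
  data.frame(pmid = pm[keep], score = unname(scores[keep]),
             rank = seq_along(keep))
}

#' Count documents matching all the given words
#'
#' The uncapped conjunctive match count used by the sensitivity-encoded
#' query selectors (the 250-row cap applies only to heatmap display).
#'
#' @param index A `corpus_index`.
#' @param words Character vector of query words.
#' @return Integer count.
#' @export
count_matches <- function(index, words) {
  stopifnot(inherits(index, "corpus_index"))
  q <- unique(tokenize(words))
  if (!length(q)) stop("empty query", call. = FALSE)
  length(conjunctive_candidates(index, q, conjunctive = TRUE))
}

#' @export
print.corpus_index <- function(x, ...) {
  cat(sprintf("<corpus_index> %d documents, %d distinct tokens\n",
              x$N, length(x$df)))
  invisible(x)
}

#' Persist a corpus index to disk
#'
#' The on-disk layout is versioned plain text: `format.json` records the
#' layout version and corpus size, `citations.jsonl` holds the citations.
#' [load_corpus_index()] rebuilds the (deterministic) index from them.
#'
#' @param index A `corpus_index`.
#' @param dir Directory to create/fill.
#' @return Invisibly, `dir`.
#' @export
save_corpus_index <- function(index, dir) {
  stopifnot(inherits(index, "corpus_index"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(format = "phenotriage-corpus-index",
         format_version = index$format_version, n_docs = index$N),
    file.path(dir, "format.json"), auto_unbox = TRUE)
  write_citations_jsonl(unname(index$citations),
                        file.path(dir, "citations.jsonl"))
  invisible(dir)
}

#' Load a corpus index saved by [save_corpus_index()]
#'
#' @param dir Directory written by [save_corpus_index()].
#' @return A `corpus_index`.
#' @export
load_corpus_index <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "format.json"))
  if (!identical(meta$format, "phenotriage-corpus-index")) {
    stop("not a corpus index directory: ", dir, call. = FALSE)
  }
  build_corpus_index(read_citations_jsonl(file.path(dir, "citations.jsonl")))
}
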