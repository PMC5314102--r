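#' Build an as-you-type suggestion index over an ontology
#'
#' Indexes every token of the name, definition, each synonym and the comment
#' of each non-obsolete term, using the shared [tokenize()] normalizer.
#' Searching all fields -- not only names -- is what lets a query like
#' "liver" surface phenotypes such as ascites whose connection to the liver
#' is stated only in their definition.
#'
#' @param collection An `ontology_collection` from [parse_obo()].
#' @return An object of class `suggester_index` with components `postings`
#'   (a data.frame of distinct `(token, term_id, field)` rows), `names`
#'   (term_id -> display name) and `n_terms`.
#' @examples
#' obo <- c("[Term]", "id: HP:0000001", "name: Ascites",
#'          'def: "Fluid accumulation, often with liver disease." []')
#' idx <- build_suggester(parse_obo(obo))
#' suggest(idx, "liver")
#' @export
build_suggester <- function(collection) {
  stopifnot(inherits(collection, "ontology_collection"))
  rows <- vector("list", length(collection$terms))
  k <- 0L
  names_map <- character(0)
  for (t in collection$terms) {
    if (t$obsolete) next
    names_map[t$term_id] <- t$name
    field_text <- list(name = t$name,
                       definition = t$definition,
                       synonym = t$synonyms,
                       comment = t$comment)
    for (f in names(field_text)) {
      toks <- unique(tokenize(field_text[[f]]))
      if (!length(toks)) next
      k <- k + 1L
      rows[[k]] <- data.frame(token = toks, term_id = t$term_id, field = f,
                              stringsAsFactors = FALSE)
    }
  }
  postings <- if (k) do.call(rbind, rows[seq_len(k)]) else
    data.frame(token = character(0), term_id = character(0),
               field = character(0), stringsAsFactors = FALSE)
  postings <- postings[order(postings$token, postings$term_id,
                             postings$field), , drop = FALSE]
  rownames(postings) <- NULL
  structure(list(postings = postings, names = names_map,
                 n_terms = length(names_map)),
            class = "suggester_index")
}

#' Suggest ontology terms for a partial query
#'
#' A term qualifies when every query word matches somewhere in its indexed
#' fields: earlier words must match whole tokens and the last word is
#' treated as a prefix, so suggestions stay useful while a word is still
#' being typed. The score is the sum of the field weights (by default
#' name > synonym > definition > comment) over the fields in which any query
#' word matched; ties break by term id ascending, so re-querying is stable.
#'
#' @param index A `suggester_index`.
#' @param partial_query Query string; may end mid-word. Empty or whitespace
#'   input yields zero suggestions.
#' @param limit Maximum suggestions returned; defaults to
#'   `config$suggestion_limit`.
#' @param config A [triage_config()].
#' @return A data.frame with columns `term_id`, `name`, `matched_fields`
#'   (list column of field names), `score` and `detail_url`, sorted by
#'   score descending.
#' @export
suggest <- function(index, partial_query, limit = NULL,
                    config = triage_config()) {
  stopifnot(inherits(index, "suggester_index"))
  assert_scalar_string(partial_query, "partial_query")
  limit <- limit %||% config$suggestion_limit
  assert_count(limit, "limit")
  empty <- data.frame(term_id = character(0), name = character(0),
                      score = numeric(0), detail_url = character(0),
                      stringsAsFactors = FALSE)
  empty$matched_fields <- list()
  empty <- empty[, c("term_id", "name", "matched_fields", "score",
                     "detail_url")]
  words <- tokenize(partial_query)
  if (!length(words)) return(empty)

  p <- index$postings
  per_word <- vector("list", length(words))
  for (i in seq_along(words)) {
    hit <- if (i == length(words)) startsWith(p$token, words[i])
           else p$token == words[i]
    per_word[[i]] <- p[hit, c("term_id", "field"), drop = FALSE]
  }
  qualifying <- Reduce(intersect, lapply(per_word, function(d)
    unique(d$term_id)))
  if (!length(qualifying)) return(empty)

  matched <- do.call(rbind, per_word)
  matched <- matched[matched$term_id %in% qualifying, , drop = FALSE]
  fields_by_term <- split(matched$field, matched$term_id)
  fields_by_term <- lapply(fields_by_term, function(f)
    intersect(names(config$field_weights), unique(f)))
  score <- vapply(fields_by_term, function(f)
    sum(config$field_weights[f]), numeric(1))

  ord <- order(-score, names(fields_by_term))
  ids <- names(fields_by_term)[ord]
  ids <- utils::head(ids, limit)
  out <- data.frame(term_id = ids, name = unname(index$names[ids]),
                    score = unname(score[ids]),
                    detail_url = vapply(ids, term_detail_url, character(1),
                                        template = config$term_url_template),
                    stringsAsFactors = FALSE)
  out$matched_fields <- unname(fields_by_term[ids])
  rownames(out) <- NULL
  out[, c("term_id", "name", "matched_fields", "score", "detail_url")]
}

#' URL of a term's entry in an external ontology browser
#'
#' @param term_id Ontology accession such as `"HP:0000952"`.
#' @param template URL template containing the placeholder `{id}` exactly
#'   once.
#' @return The URL string.
#' @examples
#' term_detail_url("HP:0000952")
#' @export
term_detail_url <- function(term_id,
                            template = triage_config()$term_url_template) {
  assert_scalar_string(term_id, "term_id")
  assert_scalar_string(template, "template")
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*:[A-Za-z0-9_.-]+$", term_id)) {
    stop("malformed term id: ", term_id, call. = FALSE)
  }
  n_ph <- length(gregexpr("{id}", template, fixed = TRUE)[[1]])
  if (!grepl("{id}", template, fixed = TRUE) || n_ph != 1L) {
    stop("`template` must contain the placeholder {id} exactly once",
         call. = FALSE)
  }
  sub("{id}", term_id, template, fixed = TRUE)
}

#' @export
print.suggester_index <- function(x, ...) {
  cat(sprintf("<suggester_index> %d terms, %d postings\n",
              x$n_terms, nrow(x$postings)))
  invisible(x)
}
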