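# Deterministic synthetic fixtures: citation corpora with exactly planted
# co-occurrence structure and OBO ontologies with planted cross-field
# matches, each emitted together with a ground-truth table sufficient to
# verify every index statistic without re-deriving it from text.
#
# Word placement is two-stage: planted membership sets are assigned exactly
# (never sampled), then background words are filled in by sampling from a
# Zipf-like rank distribution. Background vocabulary is disjoint from the
# planted words, so planted counts are exact, not expected values.

#' Specification of a synthetic citation corpus
#'
#' @param n_docs Number of citations to generate.
#' @param planted List of `list(words = <chr>, n_docs = <int>)` entries:
#'   "exactly `n_docs` documents contain all of `words`". Counts must be
#'   mutually consistent (a subset's count at least its supersets' count,
#'   accounting for overlap).
#' @param background_df Named integer vector of exact per-word document
#'   frequencies for background words, or `NULL` to derive one from
#'   `n_background_words` and `zipf_exponent`.
#' @param n_background_words Number of auto-generated background words
#'   (`bg001`, `bg002`, ...).
#' @param zipf_exponent Rank exponent of the background document-frequency
#'   curve (df of rank-r word proportional to r^-exponent), giving a
#'   realistic idf spread.
#' @param field_probs Placement probabilities over the four indexed fields.
#' @param seed Integer seed; the same seed reproduces the corpus
#'   byte-identically.
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_docs, planted = list(), background_df = NULL,
                        n_background_words = 30L, zipf_exponent = 1,
                        field_probs = c(title = 0.15, journal = 0.05,
                                        mesh = 0.2, abstract = 0.6),
                        seed = 1L) {
  assert_count(n_docs, "n_docs", positive = FALSE)
  stopifnot(is.list(planted))
  for (p in planted) {
    if (!is.character(p$words) || !length(p$words) ||
        anyDuplicated(p$words) || !is.numeric(p$n_docs) || p$n_docs < 0) {
      stop("each planted entry needs distinct `words` and `n_docs` >= 0",
           call. = FALSE)
    }
  }
  fields <- index_fields()
  if (!all(fields %in% names(field_probs)) || any(field_probs < 0)) {
    stop("`field_probs` must be non-negative and name the fields ",
         paste(fields, collapse = ", "), call. = FALSE)
  }
  if (is.null(background_df)) {
    if (n_background_words > 0) {
      words <- sprintf("bg%03d", seq_len(n_background_words))
      df <- pmax(1L, round(0.4 * n_docs *
                             seq_len(n_background_words)^(-zipf_exponent)))
      background_df <- stats::setNames(as.integer(pmin(df, max(n_docs, 1))),
                                       words)
    } else {
      background_df <- stats::setNames(integer(0), character(0))
    }
  }
  planted_words <- unique(unlist(lapply(planted, `[[`, "words")))
  if (any(names(background_df) %in% planted_words)) {
    stop("background vocabulary must be disjoint from planted words",
         call. = FALSE)
  }
  structure(list(n_docs = as.integer(n_docs), planted = planted,
                 background_df = background_df,
                 field_probs = field_probs[fields] / sum(field_probs[fields]),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

# Assign planted word sets to document slots, largest sets first, so that a
# naive scan finds exactly the requested co-occurrence counts.
plan_planted_docs <- function(spec) {
  planted <- spec$planted
  if (!length(planted)) return(list())
  sizes <- vapply(planted, function(p) length(p$words), integer(1))
  planted <- planted[order(-sizes)]
  assignments <- list()  # one character vector of words per planted doc
  for (p in planted) {
    covering <- sum(vapply(assignments, function(a)
      all(p$words %in% a), logical(1)))
    deficit <- p$n_docs - covering
    if (deficit < 0) {
      stop(sprintf(paste0(
        "inconsistent planted counts: {%s} requested in exactly %d ",
        "documents but %d already contain it via supersets"),
        paste(p$words, collapse = ","), p$n_docs, covering), call. = FALSE)
    }
    assignments <- c(assignments,
                     rep(list(p$words), deficit))
  }
  if (length(assignments) > spec$n_docs) {
    stop(sprintf("planted sets require %d documents but n_docs = %d",
                 length(assignments), spec$n_docs), call. = FALSE)
  }
  assignments
}

#' Generate a synthetic citation corpus with known ground truth
#'
#' Realizes the planted co-occurrence sets exactly, fills in background
#' words with the specified document frequencies, and composes each
#' citation's title, journal, MeSH headings and abstract from the assigned
#' tokens (plus one unique title token `doc<pmid>` and one of three shared
#' journal tokens, both recorded in the ground truth).
#'
#' @param spec A [corpus_spec()].
#' @return List with `citations` (list of `citation`) and `ground_truth`
#'   (data.frame `pmid`, `word`, `field`, `count` covering every token of
#'   every indexed field).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  assignments <- plan_planted_docs(spec)  # errors before any generation
  if (spec$n_docs == 0L) {
    return(list(citations = list(),
                ground_truth = data.frame(pmid = integer(0),
                                          word = character(0),
                                          field = character(0),
                                          count = integer(0),
                                          stringsAsFactors = FALSE)))
  }
  with_local_seed(spec$seed, {
    n <- spec$n_docs
    pmids <- 100000L + seq_len(n)
    fields <- index_fields()

    # word placements per doc: named list field -> named count vector
    placements <- lapply(seq_len(n), function(i)
      stats::setNames(vector("list", length(fields)), fields))
    gt <- list()
    add_word <- function(i, word, field, count) {
      placements[[i]][[field]][[word]] <<-
        (placements[[i]][[field]][[word]] %||% 0L) + count
      gt[[length(gt) + 1L]] <<- data.frame(
        pmid = pmids[i], word = word, field = field, count = NA_integer_,
        stringsAsFactors = FALSE)
      invisible(NULL)
    }

    # planted memberships: docs 1..length(assignments), exact
    for (i in seq_along(assignments)) {
      for (w in assignments[[i]]) {
        field <- sample(fields, 1, prob = spec$field_probs)
        count <- sample(1:3, 1, prob = c(0.7, 0.2, 0.1))
        add_word(i, w, field, count)
      }
    }
    # background words: exact df, sampled doc subsets
    for (w in names(spec$background_df)) {
      docs <- sample.int(n, spec$background_df[[w]])
      for (i in docs) {
        field <- sample(fields, 1, prob = spec$field_probs)
        count <- sample(1:3, 1, prob = c(0.7, 0.2, 0.1))
        add_word(i, w, field, count)
      }
    }
    # structural fillers: unique title token, shared journal token
    for (i in seq_len(n)) {
      add_word(i, paste0("doc", pmids[i]), "title", 1L)
      add_word(i, paste0("journal", 1L + (i %% 3L)), "journal", 1L)
    }

    citations <- vector("list", n)
    for (i in seq_len(n)) {
      pl <- placements[[i]]
      expand <- function(field) {
        v <- unlist(pl[[field]])
        if (is.null(v)) return(character(0))
        rep(names(v), times = v)
      }
      title_toks <- expand("title")
      # keep the unique doc token first for readability
      title_toks <- c(title_toks[startsWith(title_toks, "doc")],
                      sample(title_toks[!startsWith(title_toks, "doc")]))
      abstract_toks <- expand("abstract")
      if (length(abstract_toks) > 1L) abstract_toks <- sample(abstract_toks)
      citations[[i]] <- citation_record(
        pmid = pmids[i],
        title = paste(title_toks, collapse = " "),
        abstract = paste(abstract_toks, collapse = " "),
        journal = paste(expand("journal"), collapse = " "),
        year = 1990L + (i %% 30L),
        mesh_terms = expand("mesh"),
        authors = paste0("author", 1L + (i %% 7L)))
    }

    ground_truth <- do.call(rbind, gt)
    # consolidate duplicate (pmid, word, field) rows and fill exact counts
    key <- paste(ground_truth$pmid, ground_truth$word, ground_truth$field)
    ground_truth <- ground_truth[!duplicated(key), , drop = FALSE]
    ground_truth$count <- mapply(function(p, w, f) {
      as.integer(placements[[match(p, pmids)]][[f]][[w]])
    }, ground_truth$pmid, ground_truth$word, ground_truth$field)
    ground_truth <- ground_truth[order(ground_truth$pmid,
                                       ground_truth$word,
                                       ground_truth$field), , drop = FALSE]
    rownames(ground_truth) <- NULL
    list(citations = citations, ground_truth = ground_truth)
  })
}

#' Specification of a synthetic OBO ontology
#'
#' @param n_terms Number of terms.
#' @param synonym_rate Probability that a term carries one synonym.
#' @param planted_definitions List of `list(word = <chr>, n_terms = <int>)`:
#'   plant `word` in the definitions of `n_terms` terms whose name and
#'   synonym lack it, reproducing the cross-field match scenario (a query
#'   like "liver" surfacing terms such as ascites via their definition).
#' @param parent_density Probability that a term (after the first) has an
#'   `is_a` parent among earlier terms.
#' @param seed Integer seed.
#' @return A list of class `ontology_spec`.
#' @export
ontology_spec <- function(n_terms, synonym_rate = 0.3,
                          planted_definitions = list(),
                          parent_density = 0.5, seed = 1L) {
  assert_count(n_terms, "n_terms")
  stopifnot(is.numeric(synonym_rate), synonym_rate >= 0, synonym_rate <= 1,
            is.numeric(parent_density), parent_density >= 0,
            parent_density <= 1)
  for (p in planted_definitions) {
    if (!is.character(p$word) || length(p$word) != 1L ||
        !is.numeric(p$n_terms) || p$n_terms < 1) {
      stop("each planted definition needs a `word` and `n_terms` >= 1",
           call. = FALSE)
    }
  }
  structure(list(n_terms = as.integer(n_terms),
                 synonym_rate = synonym_rate,
                 planted_definitions = planted_definitions,
                 parent_density = parent_density,
                 seed = as.integer(seed)),
            class = "ontology_spec")
}

#' Generate a synthetic OBO ontology with known ground truth
#'
#' @param spec An [ontology_spec()].
#' @return List with `obo` (character vector of OBO lines), `collection`
#'   (the parsed `ontology_collection`) and `ground_truth` (data.frame
#'   `term_id`, `probe`, `field`: which probe words should match which
#'   terms via which planted field).
#' @export
generate_ontology <- function(spec) {
  stopifnot(inherits(spec, "ontology_spec"))
  with_local_seed(spec$seed, {
    adjectives <- c("progressive", "congenital", "recurrent", "chronic",
                    "focal", "diffuse", "acute", "generalized", "distal",
                    "proximal", "bilateral", "episodic")
    nouns <- c("hepatomegaly", "ascites", "fibrosis", "ophthalmoplegia",
               "anemia", "ataxia", "cardiomyopathy", "seizures",
               "nystagmus", "splenomegaly", "edema", "hypotonia")
    pairs <- expand.grid(a = adjectives, n = nouns,
                         stringsAsFactors = FALSE)
    if (spec$n_terms > nrow(pairs)) {
      stop("n_terms exceeds the name pool (", nrow(pairs), ")",
           call. = FALSE)
    }
    picked <- pairs[sample.int(nrow(pairs), spec$n_terms), , drop = FALSE]
    ids <- sprintf("HP:%07d", seq_len(spec$n_terms))
    terms <- vector("list", spec$n_terms)
    for (i in seq_len(spec$n_terms)) {
      name <- paste(picked$a[i], picked$n[i])
      synonyms <- if (stats::runif(1) < spec$synonym_rate) {
        paste(picked$n[i], "abnormality")
      } else character(0)
      parents <- if (i > 1L && stats::runif(1) < spec$parent_density) {
        ids[sample.int(i - 1L, 1L)]
      } else character(0)
      terms[[i]] <- list(term_id = ids[i], name = name,
                         definition = sprintf(
                           "A %s form of %s observed in patients.",
                           picked$a[i], picked$n[i]),
                         synonyms = synonyms, comment = "",
                         parents = parents, obsolete = FALSE)
    }
    names(terms) <- ids

    gt <- list()
    for (p in spec$planted_definitions) {
      eligible <- which(vapply(terms, function(t) {
        toks <- c(tokenize(t$name), tokenize(t$synonyms))
        !p$word %in% toks
      }, logical(1)))
      if (length(eligible) < p$n_terms) {
        stop("not enough terms lacking '", p$word,
             "' to plant its definitions", call. = FALSE)
      }
      chosen <- eligible[sample.int(length(eligible), p$n_terms)]
      for (i in chosen) {
        terms[[i]]$definition <- paste(
          terms[[i]]$definition,
          sprintf("Commonly associated with %s disease.", p$word))
        gt[[length(gt) + 1L]] <- data.frame(
          term_id = terms[[i]]$term_id, probe = p$word,
          field = "definition", stringsAsFactors = FALSE)
      }
    }
    collection <- structure(list(terms = terms, dangling = character(0)),
                            class = "ontology_collection")
    obo <- write_obo(collection)
    reparsed <- parse_obo(obo)  # generated OBO must parse cleanly
    stopifnot(length(reparsed$terms) == spec$n_terms)
    ground_truth <- if (length(gt)) do.call(rbind, gt) else
      data.frame(term_id = character(0), probe = character(0),
                 field = character(0), stringsAsFactors = FALSE)
    list(obo = obo, collection = collection, ground_truth = ground_truth)
  })
}
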