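test_that("per-field counts and document-level df are exact", {
  cit <- citation_record(1L, "Renin study",
                         abstract = "Renin is measured; renin rises.",
                         journal = "Endocrine Journal")
  idx <- build_corpus_index(list(cit))
  p <- index_postings(idx, "renin")
  expect_equal(p$count[p$field == "abstract"], 2)
  expect_equal(p$count[p$field == "title"], 1)
  expect_equal(unname(idx$df["renin"]), 1L)  # title+abstract still df = 1
})

test_that("index statistics equal a naive full recount", {
  gen <- generate_corpus(fixture_planted_spec())
  idx <- build_corpus_index(gen$citations)
  # total token mass: sum over postings == total token count of the corpus
  total_corpus <- sum(vapply(gen$citations, function(cit)
    length(unlist(oracle_doc_tokens(cit))), integer(1)))
  total_index <- sum(vapply(idx$doc_vectors, sum, numeric(1)))
  expect_equal(total_index, total_corpus)
  # df of every token matches a naive document scan
  for (tok in names(idx$df)) {
    naive <- sum(vapply(gen$citations, function(cit)
      tok %in% unlist(oracle_doc_tokens(cit)), logical(1)))
    expect_equal(unname(idx$df[tok]), naive, info = tok)
    expect_lte(unname(idx$df[tok]), idx$N)
  }
  # and the generator's ground-truth table reproduces every posting
  gt <- gen$ground_truth
  for (r in sample.int(nrow(gt), 50)) {
    p <- index_postings(idx, gt$word[r])
    got <- p$count[p$pmid == gt$pmid[r] & p$field == gt$field[r]]
    expect_equal(got, gt$count[r])
  }
})

test_that("index build is deterministic", {
  cits <- fixture_citations5()
  expect_identical(build_corpus_index(cits), build_corpus_index(cits))
})

test_that("scores match an independently coded brute-force cosine to 1e-9", {
  cits <- fixture_citations5()
  idx <- build_corpus_index(cits)
  for (q in list(c("renin", "hypertension"), "fibrosis",
                 c("progressive", "external", "ophthalmoplegia"),
                 c("renin", "nosuchtoken"))) {
    oracle <- oracle_scores(cits, q)
    for (pm in names(oracle)) {
      expect_equal(score_document(idx, q, as.integer(pm)),
                   unname(oracle[pm]), tolerance = 1e-9,
                   info = paste(paste(q, collapse = "+"), pm))
    }
  }
})

test_that("a document with no query token scores zero", {
  idx <- build_corpus_index(fixture_citations5())
  expect_equal(score_document(idx, "ophthalmoplegia", 102L), 0)
})

test_that("identical documents score identically", {
  twins <- list(
    citation_record(1L, "Same title", abstract = "Same abstract renin.",
                    journal = "J", mesh_terms = "Renin"),
    citation_record(2L, "Same title", abstract = "Same abstract renin.",
                    journal = "J", mesh_terms = "Renin"),
    citation_record(3L, "Other things entirely", abstract = "Unrelated."))
  idx <- build_corpus_index(twins)
  expect_equal(score_document(idx, c("renin", "same"), 1L),
               score_document(idx, c("renin", "same"), 2L))
})

test_that("scores are invariant to query order and duplicates", {
  idx <- build_corpus_index(fixture_citations5())
  q <- c("renin", "hypertension")
  expect_equal(score_document(idx, q, 101L),
               score_document(idx, rev(q), 101L))
  expect_equal(score_document(idx, q, 101L),
               score_document(idx, c(q, q, "renin"), 101L))
})

test_that("scoring an unknown pmid and searching an empty query error", {
  idx <- build_corpus_index(fixture_citations5())
  expect_error(score_document(idx, "renin", 999L), "unknown pmid")
  expect_error(search_index(idx, character(0)), "empty query")
  expect_error(search_index(idx, "..."), "empty query")
})

test_that("search ordering equals the oracle ordering on the 5-doc fixture", {
  cits <- fixture_citations5()
  idx <- build_corpus_index(cits)
  q <- c("renin", "hypertension")
  hits <- search_index(idx, q, conjunctive = FALSE, cap = Inf)
  oracle <- oracle_scores(cits, q)
  oracle <- oracle[oracle > 0]
  ord <- order(-oracle, -as.integer(names(oracle)))
  expect_equal(hits$pmid, as.integer(names(oracle))[ord])
  expect_equal(hits$score, unname(oracle[ord]), tolerance = 1e-9)
  expect_equal(hits$rank, seq_len(nrow(hits)))
})

test_that("conjunctive hits are contained in disjunctive hits", {
  idx <- build_corpus_index(generate_corpus(fixture_planted_spec())$citations)
  q <- c("a1", "b1")
  conj <- search_index(idx, q, conjunctive = TRUE, cap = Inf)$pmid
  disj <- search_index(idx, q, conjunctive = FALSE, cap = Inf)$pmid
  expect_true(all(conj %in% disj))
  # AND semantics: every conjunctive hit contains every token
  for (pm in conj) {
    v <- idx$doc_vectors[[as.character(pm)]]
    expect_true(all(q %in% names(v)))
  }
})

test_that("adding a conjunctive token never grows the candidate set", {
  idx <- build_corpus_index(generate_corpus(fixture_planted_spec())$citations)
  n1 <- nrow(search_index(idx, "b1", cap = Inf))
  n2 <- nrow(search_index(idx, c("b1", "a1"), cap = Inf))
  n3 <- nrow(search_index(idx, c("b1", "a1", "c1"), cap = Inf))
  expect_gte(n1, n2)
  expect_gte(n2, n3)
})

test_that("capped search equals the head of uncapped search", {
  idx <- build_corpus_index(generate_corpus(fixture_planted_spec())$citations)
  all_hits <- search_index(idx, "b1", cap = Inf)
  for (k in c(1, 3, 10)) {
    capped <- search_index(idx, "b1", cap = k)
    expect_equal(capped$pmid, utils::head(all_hits$pmid, k))
  }
})

test_that("the default display cap truncates large result sets to 250", {
  spec <- corpus_spec(300, planted = list(
    list(words = c("q1", "q2"), n_docs = 280L)),
    n_background_words = 10L, seed = 23)
  idx <- build_corpus_index(generate_corpus(spec)$citations)
  expect_equal(count_matches(idx, c("q1", "q2")), 280L)
  hits <- search_index(idx, c("q1", "q2"))
  expect_equal(nrow(hits), 250L)
})

test_that("score ties break by pmid descending", {
  twins <- list(
    citation_record(5L, "alpha beta", abstract = "gamma"),
    citation_record(9L, "alpha beta", abstract = "gamma"),
    citation_record(2L, "alpha beta", abstract = "gamma"))
  idx <- build_corpus_index(twins)
  expect_equal(search_index(idx, "alpha", cap = Inf)$pmid, c(9L, 5L, 2L))
})

test_that("the persisted index layout reloads to an identical index", {
  idx <- build_corpus_index(fixture_citations5())
  dir <- withr::local_tempdir()
  save_corpus_index(idx, dir)
  expect_identical(load_corpus_index(dir), idx)
})
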