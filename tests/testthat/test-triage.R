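triage_fixture <- function() {
  gen <- generate_corpus(fixture_planted_spec())
  idx <- build_corpus_index(gen$citations)
  list(gen = gen, idx = idx,
       hits = search_index(idx, c("a1", "b1"), cap = Inf),
       words = c("a1", "b1", "c1"))
}

test_that("heatmap dimensions and counts match a naive recount", {
  fx <- triage_fixture()
  hits6 <- utils::head(fx$hits, 6)
  hm <- build_heatmap(fx$idx, hits6, fx$words)
  expect_equal(dim(hm$counts), c(6L, 3L))
  expect_equal(hm$color_index, 1:3)
  cits <- fx$idx$citations
  for (i in seq_along(hm$pmids)) {
    toks <- unlist(oracle_doc_tokens(cits[[as.character(hm$pmids[i])]]))
    for (j in seq_along(hm$words)) {
      expect_equal(unname(hm$counts[i, j]), sum(toks == hm$words[j]))
    }
  }
  # conjunctive query words occur in every row
  expect_true(all(hm$counts[, "a1"] >= 1))
  expect_true(all(hm$counts[, "b1"] >= 1))
})

test_that("saturation is per-column count / column max, white iff zero", {
  fx <- triage_fixture()
  hm <- build_heatmap(fx$idx, utils::head(fx$hits, 10), fx$words)
  for (j in seq_along(hm$words)) {
    cmax <- max(hm$counts[, j])
    expected <- if (cmax > 0) hm$counts[, j] / cmax else hm$counts[, j] * 0
    expect_equal(hm$saturation[, j], expected)
    if (cmax > 0) expect_equal(max(hm$saturation[, j]), 1)
  }
  expect_identical(hm$saturation == 0, hm$counts == 0)
})

test_that("an empty hit list gives a valid empty heatmap", {
  fx <- triage_fixture()
  hm <- build_heatmap(fx$idx, fx$hits[0, ], fx$words)
  expect_equal(dim(hm$counts), c(0L, 3L))
  expect_equal(hm$words, fx$words)
})

test_that("term distribution counts the four metadata places", {
  cit <- citation_record(1L, "Renin in kidney",
                         abstract = "Renin renin and more renin.",
                         journal = "Journal of Renin Research",
                         mesh_terms = c("Renin", "Kidney Diseases"))
  td <- term_distribution(cit, c("renin", "kidney", "absent"))
  expect_equal(unname(td$counts[, "renin"]), c(1, 1, 1, 3))
  expect_equal(unname(td$counts["mesh", "kidney"]), 1)
  expect_equal(unname(td$counts[, "absent"]), c(0, 0, 0, 0))
  # a word only in the journal name: (0, k, 0, 0)
  td2 <- term_distribution(cit, "research")
  expect_equal(unname(td2$counts[, "research"]), c(0, 1, 0, 0))
  expect_equal(td$metadata$title, cit$title)
})

test_that("heatmap pooled counts reconcile with distribution and spans", {
  fx <- triage_fixture()
  hm <- build_heatmap(fx$idx, utils::head(fx$hits, 15), fx$words)
  for (i in seq_along(hm$pmids)) {
    cit <- fx$idx$citations[[as.character(hm$pmids[i])]]
    td <- term_distribution(cit, fx$words)
    spans <- encode_abstract(cit, fx$words)
    for (j in seq_along(fx$words)) {
      w <- fx$words[j]
      expect_equal(sum(td$counts[, w]), unname(hm$counts[i, j]))
      expect_equal(sum(spans$word == w),
                   unname(td$counts["abstract", w]))
    }
  }
})

test_that("abstract spans are exact, sorted and non-overlapping", {
  cit <- citation_record(1L, "t",
    abstract = "Renin and renin levels; renin-angiotensin axis.")
  spans <- encode_abstract(cit, c("renin", "axis"))
  expect_equal(sum(spans$word == "renin"), 3L)
  expect_equal(sum(spans$word == "axis"), 1L)
  for (i in seq_len(nrow(spans))) {
    expect_equal(tolower(substr(cit$abstract, spans$start[i],
                                spans$end[i])), spans$word[i])
  }
  expect_true(all(diff(spans$start) > 0))
  expect_true(all(spans$start[-1] > spans$end[-nrow(spans)]))
  # word_index ties spans to heatmap column order
  expect_equal(unique(spans$word_index[spans$word == "renin"]), 1L)
  expect_equal(unique(spans$word_index[spans$word == "axis"]), 2L)
  # token-boundary: "axis" does not match inside "taxis"
  cit2 <- citation_record(2L, "t", abstract = "Taxis and axis.")
  expect_equal(nrow(encode_abstract(cit2, "axis")), 1L)
  # empty abstract
  expect_equal(nrow(encode_abstract(citation_record(3L, "t"), "renin")), 0L)
})

test_that("dwell accumulates across visits and marks at the threshold", {
  fx <- triage_fixture()
  s <- new_triage_session(fx$idx, c("a1", "b1"))
  pm <- s$candidates[1]
  s <- record_dwell(s, pm, 4.99)
  expect_false(pm %in% s$visited)
  s <- record_dwell(s, pm, 0.01)
  expect_true(pm %in% s$visited)
  s0 <- record_dwell(new_triage_session(fx$idx, c("a1", "b1")), pm, 0)
  expect_false(pm %in% s0$visited)
  expect_error(record_dwell(s, 999999L, 1), "unknown pmid")
  expect_error(record_dwell(s, pm, -1), "non-negative")
})

test_that("threshold probing finds 5 s as the smallest marking dwell", {
  fx <- triage_fixture()
  pm <- search_index(fx$idx, c("a1", "b1"))$pmid[1]
  marking <- vapply(seq(0.5, 10, by = 0.5), function(sec) {
    s <- new_triage_session(fx$idx, c("a1", "b1"))
    s <- record_dwell(s, pm, sec)
    pm %in% s$visited
  }, logical(1))
  expect_equal(min(seq(0.5, 10, by = 0.5)[marking]), 5)
})

test_that("selection is order-preserving and idempotent; stage walk works", {
  fx <- triage_fixture()
  s <- new_triage_session(fx$idx, c("a1", "b1"))
  picks <- s$candidates[c(3, 1, 5)]
  for (p in picks) s <- select_document(s, p)
  expect_equal(s$selected_pile, picks)
  s <- select_document(s, picks[2])
  expect_equal(s$selected_pile, picks)            # idempotent
  expect_error(select_document(s, 1L), "not a candidate")
  expect_error(advance_stage(new_triage_session(fx$idx, c("a1", "b1"))),
               "pile is empty")

  s <- advance_stage(s)
  expect_equal(s$stage, "individual_document")
  expect_error(advance_stage(s), "no reading document")
  s <- read_document(s, picks[1])
  s <- advance_stage(s)
  expect_equal(s$stage, "further_reading")
  expect_error(advance_stage(s), "last stage")
  expect_error(read_document(s, s$candidates[2]), "not in the selected pile")

  # retreat to any earlier stage preserves all state
  s2 <- retreat_stage(s, to = "multiple_document")
  expect_equal(s2$selected_pile, picks)
  expect_equal(s2$reading, picks[1])
  expect_equal(s2$visited, s$visited)
})

test_that("rejection removes from the pile at stage 2 only", {
  fx <- triage_fixture()
  s <- new_triage_session(fx$idx, c("a1", "b1"))
  picks <- s$candidates[1:3]
  for (p in picks) s <- select_document(s, p)
  # stage 1: rejecting a candidate never touches the pile
  s1 <- reject_document(s, s$candidates[4])
  expect_equal(s1$selected_pile, picks)
  s <- advance_stage(s)
  s <- read_document(s, picks[2])
  s <- reject_document(s, picks[2])
  expect_equal(s$selected_pile, picks[c(1, 3)])
  expect_true(is.na(s$reading))                   # reading focus cleared
  expect_error(reject_document(s, picks[2]), "not in the current working set")
})

test_that("cursor navigation clamps at both ends", {
  fx <- triage_fixture()
  s <- new_triage_session(fx$idx, c("a1", "b1"))
  n <- length(s$candidates)
  s <- navigate(s, "prev")
  expect_equal(s$cursor, 1L)
  for (i in seq_len(n + 5)) s <- navigate(s, "next")
  expect_equal(s$cursor, n)
  expect_equal(current_document(s), s$candidates[n])
})

test_that("retreat and re-advance reproduce byte-identical stage payloads", {
  fx <- triage_fixture()
  s <- new_triage_session(fx$idx, c("a1", "b1"))
  for (p in s$candidates[1:4]) s <- select_document(s, p)
  s <- advance_stage(s)
  s <- read_document(s, s$selected_pile[1])
  p1 <- stage_payload(s)
  s <- retreat_stage(s)
  s <- advance_stage(s)
  p2 <- stage_payload(s)
  expect_identical(serialize(p1, NULL), serialize(p2, NULL))
})

test_that("random 1000-event sessions never violate the invariants", {
  fx <- triage_fixture()
  set.seed(404)
  s <- new_triage_session(fx$idx, c("a1", "b1"))
  visited_sizes <- integer(0)
  ops <- c("navigate", "dwell", "select", "reject", "read", "advance",
           "retreat")
  for (k in seq_len(1000)) {
    op <- sample(ops, 1)
    s <- tryCatch(switch(op,
      navigate = navigate(s, sample(c("next", "prev"), 1)),
      dwell = record_dwell(s, sample(s$candidates, 1), stats::runif(1, 0, 4)),
      select = {
        if (s$stage == "multiple_document")
          select_document(s, sample(s$candidates, 1)) else s
      },
      reject = {
        ws <- if (s$stage == "multiple_document") s$candidates
              else s$selected_pile
        if (length(ws)) reject_document(s, sample(ws, 1)) else s
      },
      read = {
        if (length(s$selected_pile))
          read_document(s, sample(s$selected_pile, 1)) else s
      },
      advance = advance_stage(s),
      retreat = retreat_stage(s)),
      error = function(e) s)  # forbidden moves must leave state untouched
    expect_no_error(validate_session(s))
    visited_sizes <- c(visited_sizes, length(s$visited))
  }
  # visited set is monotone nondecreasing over the whole run
  expect_true(all(diff(visited_sizes) >= 0))
})

test_that("sessions round-trip through the versioned JSON file", {
  fx <- triage_fixture()
  s <- new_triage_session(fx$idx, c("a1", "b1"))
  s <- record_dwell(s, s$candidates[1], 7)
  for (p in s$candidates[1:2]) s <- select_document(s, p)
  s <- advance_stage(s)
  f <- withr::local_tempfile(fileext = ".json")
  save_triage_session(s, f)
  s2 <- load_triage_session(f, fx$idx)
  s$config <- NULL; s2$config <- NULL
  s$index <- NULL; s2$index <- NULL
  expect_equal(s2, s)
})

test_that("PubMed URLs are templated, validated and injective", {
  expect_equal(pubmed_url(12345), "https://pubmed.ncbi.nlm.nih.gov/12345/")
  expect_equal(pubmed_url(7, template = "x/{pmid}"), "x/7")
  expect_error(pubmed_url(0), "positive integer")
  expect_error(pubmed_url(5, template = "no placeholder"), "placeholder")
  fx <- triage_fixture()
  urls <- vapply(fx$hits$pmid, pubmed_url, character(1))
  expect_equal(anyDuplicated(urls), 0L)
})
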