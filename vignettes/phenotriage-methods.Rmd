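---
title: "Methods: ontology-driven search and staged document triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology-driven search and staged document triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotriage)
```

## Overview

`phenotriage` models exploratory biomedical literature search as two
phases. In the vocabulary-building phase, an ontology of phenotypes supplies
the words a user lacks: as-you-type suggestions are matched against every
text field of every term, and a sensitivity-encoded expansion shows how the
result set would change under every relaxation of a chosen phenotype name.
In the triaging phase, ranked results flow through three stages —
multiple-document scanning, individual-document inspection, further
reading — each backed by a concrete data structure this package computes.
This vignette records the model, the tunable parameters, the design
decisions taken where behavior was genuinely open, and what the synthetic
fixtures do and do not demonstrate.

## Text normalization

One tokenizer (`tokenize()`) is shared by the suggester, the corpus index,
the expansion and every triage view: lowercase, split on runs of
non-alphanumeric characters, no stemming, no spelling normalization. The
shared normalizer is load-bearing — matched fields reported by the
suggester, heatmap counts, distribution-matrix counts and abstract spans
are all mutually verifiable only because they count the same tokens.
Deliberately, orthographic variants ("ophthalmoplegia" vs
"opthalmoplegia") remain distinct tokens: the engine never second-guesses
the query, and the sensitivity expansion exists precisely to let users
explore such variation explicitly. Exact-prefix matching (no fuzzy or
stemmed matching) is used for suggestions for the same reason.

## Ontology indexing and suggestion ranking

`parse_obo()` reads OBO 1.2/1.4 `[Term]` stanzas (id, name, def, synonym,
comment, is_a, is_obsolete; unknown tags ignored; synonym scopes stripped).
Obsolete terms are parsed and flagged but never indexed for suggestion.
`build_suggester()` posts every distinct (token, field) pair per term.

A suggestion query qualifies a term when each query word matches somewhere
in the term's fields — earlier words as whole tokens, the final word as a
prefix (it may still be mid-typing). The score is the sum of weights over
the distinct fields in which any query word matched, with defaults
name = 4, synonym = 3, definition = 2, comment = 1 and ties broken by term
id ascending. These weights are a design choice, not an empirical fit: a
match in the displayed name should outrank one buried in commentary, and an
additive rule keeps scores explainable ("matched in name and definition").
The weights and the suggestion limit (default 25) are configurable via
`triage_config()`.

## Corpus indexing and ranking

Citations carry pmid, title, abstract, journal, year, MeSH descriptors and
authors; title, journal, MeSH and abstract are indexed (authors and year
are display metadata). The ranking is a classic vector space model with
Lucene-style weighting:

* document weight `sqrt(tf) * idf` with `tf` pooled over the four fields,
* query weight `idf` per distinct query token,
* `idf = 1 + ln(N / (1 + df))` with document-level `df`,
* score = cosine of the two vectors.

Two deliberate simplifications: fields are pooled into one bag per document
(no per-field boosts — per-field counts are kept separately for the triage
views), and no coordination factor or length-norm quirks are layered on
top. The variant was chosen for transparency and testability: every score
in the test suite is reproduced to 1e-9 by an independently coded dense
brute-force cosine.

Search semantics are conjunctive by default — a document must contain every
query token, in any field — matching how phenotype words are combined
during triage; disjunctive (any-token) search is available. Ties in score
break by PMID descending, preferring newer citations. Match counting for
the expansion is always uncapped; only heatmap display truncates, at the
cap of 250 ranked documents.

## Sensitivity-encoded expansion

A phenotype name is reduced to distinct, stopword-free words
(`phenotype_words()`; the stopword list is small, fixed, English and
config-visible — "congenital fibrosis **of** extraocular muscles"
contributes four words). All `2^n − 1` non-empty word subsets are
enumerated, largest first, capped at n = 6 words per phenotype to bound the
blow-up (real phenotype names rarely exceed four content words). Each
subset's row reports its uncapped conjunctive count, the count minus the
full set's count (the "additional articles" a relaxation reaches — never
negative, by anti-monotonicity of conjunctive matching), and a bar fraction
linear in count and normalized to the largest emitted row. With several
phenotypes selected, each is expanded separately over its own words;
the pooled distinct words of all selections define the heatmap columns.

## Triage data model

**Query-result heatmap.** Rows are the ranked documents (≤ 250), columns
the pooled query words with stable color indices assigned in word order.
Cell counts pool the four fields; saturation is count divided by the column
maximum over displayed rows, so saturation 0 is exactly "word absent" and
each non-empty column attains 1. Per-column normalization was chosen
because raw counts differ wildly between common and rare words; a global
scale would flatten rare-word columns to near-white.

**Term-distribution matrix.** For one document, each query word's count in
each of the four metadata places (title, journal name, MeSH terms, abstract
text), plus the displayed metadata. Its column sums equal the heatmap cell
counts by construction, and the test suite enforces that reconciliation.

**Term-encoded abstract.** 1-based, inclusive, non-overlapping character
spans of every token-boundary, case-insensitive query-word occurrence in
the abstract, tagged with the word's column color index. Span counts per
word equal the distribution matrix's abstract row.

**Session state machine.** Stage 1 (multiple-document) navigates the
candidates; selecting appends to an order-preserving, idempotent pile.
Stage 2 (individual-document) navigates the pile; the orange-"x" reject
removes from the pile. Stage 3 (further-reading) focuses one pile document
and exposes its external PubMed URL. Advancing requires a non-empty pile
(stage 1→2) and a reading focus (stage 2→3); retreating to any earlier
stage preserves all state, and invariants (pile ⊆ candidates, reading ∈
pile, visited only above-threshold documents, cursor in range) are
re-checked after every scripted event.

Two behaviors were genuinely open and are resolved as follows. Dwell time
*accumulates* across repeat visits, and a document is marked visited exactly
when accumulated dwell reaches the threshold (default 5 s): accumulation is
the more conservative reading of "paused for 5 s or more" for a reminder
mark, since three 2-second glances convey as much familiarity as one
6-second pause. And rejection at stage 1 is a recorded no-op — a candidate
not selected simply never enters the pile — while the explicit reject
affordance lives at stage 2, where an earlier selection is being revised.

## Synthetic fixtures

`generate_corpus()` and `generate_ontology()` make the whole engine
testable offline. Word placement is two-stage: planted co-occurrence sets
("exactly 10 documents contain all of {a, b, c}") are assigned to document
slots deterministically, largest sets first, with inconsistent requests
rejected before generation; background words are then sampled with exact
per-word document frequencies following a Zipf-like rank curve (exponent 1
by default) to give a realistic idf spread. Planted and background
vocabularies are disjoint, so planted counts are exact rather than
expected values. Every generated token is recorded in a ground-truth table
(pmid, word, field, count) sufficient to verify df, tf and all view counts
without re-deriving them from text. All randomness flows through the
spec's single seed, generation is byte-reproducible, and the caller's RNG
stream is left untouched.

What the fixtures do *not* emulate: real MEDLINE scale (tens of millions
of citations), natural-language abstracts (generated abstracts are bags of
tokens), real HPO content and its deep is_a hierarchy, or real word
burstiness and correlation structure. Passing tests therefore demonstrate
the correctness of the indexing, counting, ranking and state-machine logic
under controlled term-frequency structure — not retrieval effectiveness on
natural text, which depends on corpus-specific statistics no synthetic
generator reproduces.

## Numerical and degenerate-input choices

* `idf = 1 + ln(N/(1 + df))` is smoothed, finite for unseen tokens, and can
  go slightly negative only when `df = N` in tiny corpora — harmless for
  ranking, and covered by the brute-force equivalence tests.
* Duplicate query tokens collapse before weighting; scores are invariant to
  query order.
* Empty corpora, empty hit lists, empty abstracts and empty ontologies all
  produce valid empty structures, not errors; empty *queries* error, since
  a query with no tokens has no meaningful candidate set.
* Documents with no tokens have zero norm and score 0 against any query.
* Suggestion and search orderings are total (score, then id) so repeated
  calls are stable.

## Problem sizes

The test suite and the acceptance script run on corpora of 5–300 documents
and ontologies of 15–40 terms, with a 1000-event session fuzz; these sizes
fully exercise every code path (the cap, the threshold, all subset chains,
all three stages) while keeping the whole suite in the tens of seconds.
The index structures are in-memory lists keyed by token and PMID,
comfortable up to corpora several orders of magnitude larger than the
fixtures; a production deployment at full MEDLINE scale would swap the
storage layer, not the model.

## Known limitations

* OBO flat files only; OWL ontologies are out of scope.
* No stemming, spelling correction or fuzzy suggestion matching (see
  above); synonym-based *query* expansion is likewise out of scope — the
  expansion operates on the selected name's own words.
* Abstract-and-metadata indexing only; no full-text.
* The engine computes visualization payloads (counts, saturations, color
  indices, spans); rendering is a front end's job and is not reproduced.
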