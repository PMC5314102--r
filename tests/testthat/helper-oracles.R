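# Shared fixtures and independent brute-force oracles. The oracles
# deliberately share no code with the package internals: they tokenize via
# regmatches() and compute tf-idf cosines on a dense term-document matrix.

# --- independent tokenizer (regex extraction, not strsplit) ---------------
oracle_tokenize <- function(text) {
  if (!length(text)) return(character(0))
  unlist(regmatches(tolower(text), gregexpr("[a-z0-9]+", tolower(text))),
         use.names = FALSE)
}

oracle_doc_tokens <- function(cit) {
  list(title = oracle_tokenize(cit$title),
       journal = oracle_tokenize(cit$journal),
       mesh = oracle_tokenize(cit$mesh_terms),
       abstract = oracle_tokenize(cit$abstract))
}

# --- dense brute-force tf-idf cosine --------------------------------------
# document weight sqrt(pooled tf) * idf, query weight idf,
# idf = 1 + ln(N / (1 + df)), cosine of the two vectors.
oracle_scores <- function(citations, query_words) {
  N <- length(citations)
  per_doc <- lapply(citations, function(cit)
    unlist(oracle_doc_tokens(cit), use.names = FALSE))
  vocab <- sort(unique(unlist(per_doc)))
  tf <- matrix(0, nrow = N, ncol = length(vocab),
               dimnames = list(NULL, vocab))
  for (i in seq_len(N)) {
    for (tok in per_doc[[i]]) tf[i, tok] <- tf[i, tok] + 1
  }
  df <- colSums(tf > 0)
  idf <- 1 + log(N / (1 + df))
  W <- sweep(sqrt(tf), 2, idf, `*`)
  doc_norm <- sqrt(rowSums(W^2))
  q <- unique(oracle_tokenize(query_words))
  qidf <- vapply(q, function(t) {
    d <- if (t %in% vocab) df[[t]] else 0
    1 + log(N / (1 + d))
  }, numeric(1))
  q_norm <- sqrt(sum(qidf^2))
  scores <- numeric(N)
  for (i in seq_len(N)) {
    dot <- 0
    for (k in seq_along(q)) {
      if (q[k] %in% vocab && tf[i, q[k]] > 0) {
        dot <- dot + sqrt(tf[i, q[k]]) * idf[[q[k]]] * qidf[k]
      }
    }
    scores[i] <- if (dot > 0 && doc_norm[i] > 0) {
      dot / (doc_norm[i] * q_norm)
    } else 0
  }
  stats::setNames(scores, vapply(citations, `[[`, integer(1), "pmid"))
}

# naive conjunctive match count over any field
oracle_count <- function(citations, words) {
  words <- unique(oracle_tokenize(words))
  sum(vapply(citations, function(cit) {
    toks <- unlist(oracle_doc_tokens(cit), use.names = FALSE)
    all(words %in% toks)
  }, logical(1)))
}

# --- hand-written fixtures ------------------------------------------------
fixture_obo <- function() {
  c("format-version: 1.2",
    "",
    "[Term]",
    "id: HP:0000001",
    "name: Hepatomegaly",
    'def: "Abnormally increased size of the liver." [PMID:1]',
    'synonym: "Enlarged liver" EXACT []',
    "comment: Often detected on physical examination.",
    "",
    "[Term]",
    "id: HP:0000002",
    "name: Ascites",
    'def: "Accumulation of fluid, commonly associated with liver disease." []',
    "is_a: HP:0000001 ! Hepatomegaly",
    "",
    "[Term]",
    "id: HP:0000003",
    "name: Splenomegaly",
    'def: "Abnormal increased size of the spleen." []',
    "is_a: HP:0000002",
    "",
    "[Term]",
    "id: HP:0000099",
    "name: Old liver sign",
    "is_obsolete: true",
    "")
}

# five documents with hand-chosen token overlap for ranking oracles
fixture_citations5 <- function() {
  list(
    citation_record(101L, "Renin and hypertension in chronic disease",
                    abstract = "Renin renin levels rise in hypertension.",
                    journal = "Journal of Hypertension", year = 2001L,
                    mesh_terms = c("Renin", "Hypertension")),
    citation_record(102L, "Hypertension outcomes",
                    abstract = "Blood pressure and hypertension outcomes.",
                    journal = "Circulation", year = 2005L,
                    mesh_terms = "Hypertension"),
    citation_record(103L, "Renal fibrosis mechanisms",
                    abstract = "Fibrosis of the kidney involves renin.",
                    journal = "Kidney International", year = 2010L,
                    mesh_terms = c("Fibrosis", "Kidney")),
    citation_record(104L, "Progressive external ophthalmoplegia cases",
                    abstract = paste("Progressive external ophthalmoplegia",
                                     "with mitochondrial deletions."),
                    journal = "Neurology", year = 1999L,
                    mesh_terms = "Ophthalmoplegia"),
    citation_record(105L, "Hypertension and renin interplay",
                    abstract = "Renin drives hypertension in some patients.",
                    journal = "Journal of Hypertension", year = 2015L,
                    mesh_terms = c("Renin", "Hypertension")))
}

fixture_medline_xml <- function() {
  paste0(
    '<?xml version="1.0"?>\n<PubmedArticleSet>\n',
    "<PubmedArticle><MedlineCitation><PMID>201</PMID><Article>",
    "<Journal><Title>Neurology</Title><JournalIssue><PubDate>",
    "<Year>1998</Year></PubDate></JournalIssue></Journal>",
    "<ArticleTitle>Ophthalmoplegia in mitochondrial disease</ArticleTitle>",
    "<Abstract><AbstractText>Part one.</AbstractText>",
    "<AbstractText>Part two.</AbstractText>",
    "<AbstractText>Part three.</AbstractText></Abstract>",
    "<AuthorList><Author><LastName>Smith</LastName>",
    "<Initials>J</Initials></Author></AuthorList></Article>",
    "<MeshHeadingList><MeshHeading>",
    "<DescriptorName>Ophthalmoplegia</DescriptorName></MeshHeading>",
    "<MeshHeading><DescriptorName>DNA, Mitochondrial</DescriptorName>",
    "</MeshHeading></MeshHeadingList>",
    "</MedlineCitation></PubmedArticle>\n",
    "<PubmedArticle><MedlineCitation><PMID>202</PMID><Article>",
    "<Journal><Title>Brain</Title><JournalIssue><PubDate>",
    "<MedlineDate>2000 Jan-Feb</MedlineDate></PubDate></JournalIssue>",
    "</Journal>",
    "<ArticleTitle>Muscle fibrosis review</ArticleTitle></Article>",
    "</MedlineCitation></PubmedArticle>\n",
    "</PubmedArticleSet>\n")
}

# planted corpus shared by expansion / acceptance tests:
# exactly 10 docs contain {a1,b1,c1}, 14 contain {a1,b1}, 20 contain {b1,c1}
fixture_planted_spec <- function(seed = 11L, n_docs = 60L) {
  corpus_spec(n_docs, planted = list(
    list(words = c("a1", "b1", "c1"), n_docs = 10L),
    list(words = c("a1", "b1"), n_docs = 14L),
    list(words = c("b1", "c1"), n_docs = 20L)),
    seed = seed)
}
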