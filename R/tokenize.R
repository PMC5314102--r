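#' Normalize text into search tokens
#'
#' The single normalizer shared by the ontology suggester, the corpus index,
#' the combination expander and every triage view: text is lowercased and
#' split on runs of non-alphanumeric characters. No stemming or spelling
#' normalization is applied, so e.g. "ophthalmoplegia" and "opthalmoplegia"
#' are distinct tokens.
#'
#' @param text Character vector; elements are tokenized independently and
#'   concatenated.
#' @return Character vector of lowercase tokens; `character(0)` for empty or
#'   fully non-alphanumeric input.
#' @examples
#' tokenize("Progressive external ophthalmoplegia.")
#' tokenize("")
#' @export
tokenize <- function(text) {
  if (length(text) == 0L) return(character(0))
  text <- text[!is.na(text)]
  if (length(text) == 0L) return(character(0))
  toks <- unlist(strsplit(tolower(text), "[^a-z0-9]+"), use.names = FALSE)
  toks[nzchar(toks)]
}

#' Default English stopword list
#'
#' A fixed, deliberately small list of English function words removed from
#' phenotype names before combination expansion and heatmap-column pooling
#' (e.g. "of" in "congenital fibrosis of extraocular muscles" is not a query
#' term). Exposed so that configurations can inspect or override it.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  c("a", "an", "and", "as", "at", "be", "but", "by", "for", "from", "in",
    "into", "is", "it", "of", "on", "or", "that", "the", "their", "then",
    "to", "with", "without")
}
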