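#' Engine configuration
#'
#' Collects every tunable constant of the search-and-triage engine in one
#' validated object. All defaults are overridable per call site; functions
#' accepting a `config` argument fall back to `triage_config()` when it is
#' omitted.
#'
#' Defaults:
#' * `suggestion_limit` (25): maximum suggestions returned per query.
#' * `field_weights` (name 4, synonym 3, definition 2, comment 1): additive
#'   score contribution of each ontology field a suggestion matched in.
#' * `stopwords`: see [default_stopwords()].
#' * `heatmap_cap` (250): maximum documents shown in the query-result
#'   heatmap; search results are truncated to this many rows for display.
#' * `dwell_threshold_s` (5): accumulated seconds of dwell after which a
#'   document is marked visited.
#' * `combo_word_limit` (6): maximum words per phenotype for combination
#'   enumeration (2^n - 1 subsets are generated).
#' * `term_url_template` / `pubmed_url_template`: URL templates with an
#'   `{id}` / `{pmid}` placeholder for external detail pages.
#' * `seed` (1): default seed for the synthetic-fixture generators.
#'
#' @param suggestion_limit Positive integer.
#' @param field_weights Named numeric vector with entries `name`, `synonym`,
#'   `definition`, `comment`, all positive.
#' @param stopwords Character vector of lowercase stopwords.
#' @param heatmap_cap Positive integer.
#' @param dwell_threshold_s Positive real, in seconds.
#' @param combo_word_limit Positive integer.
#' @param term_url_template Template string containing `{id}` exactly once.
#' @param pubmed_url_template Template string containing `{pmid}` exactly
#'   once.
#' @param seed Integer seed.
#' @return A list of class `triage_config`.
#' @examples
#' cfg <- triage_config(heatmap_cap = 100)
#' cfg$heatmap_cap
#' @export
triage_config <- function(suggestion_limit = 25L,
                          field_weights = c(name = 4, synonym = 3,
                                            definition = 2, comment = 1),
                          stopwords = default_stopwords(),
                          heatmap_cap = 250L,
                          dwell_threshold_s = 5,
                          combo_word_limit = 6L,
                          term_url_template =
                            "https://hpo.jax.org/app/browse/term/{id}",
                          pubmed_url_template =
                            "https://pubmed.ncbi.nlm.nih.gov/{pmid}/",
                          seed = 1L) {
  assert_count(suggestion_limit, "suggestion_limit")
  assert_count(heatmap_cap, "heatmap_cap")
  assert_count(combo_word_limit, "combo_word_limit")
  if (!is.numeric(dwell_threshold_s) || length(dwell_threshold_s) != 1L ||
      is.na(dwell_threshold_s) || dwell_threshold_s <= 0) {
    stop("`dwell_threshold_s` must be a positive number of seconds",
         call. = FALSE)
  }
  needed <- c("name", "synonym", "definition", "comment")
  if (!is.numeric(field_weights) || !all(needed %in% names(field_weights)) ||
      any(field_weights[needed] <= 0)) {
    stop("`field_weights` must be positive and name all of: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!is.character(stopwords)) stop("`stopwords` must be a character vector",
                                     call. = FALSE)
  assert_scalar_string(term_url_template, "term_url_template")
  assert_scalar_string(pubmed_url_template, "pubmed_url_template")
  if (!grepl("{id}", term_url_template, fixed = TRUE)) {
    stop("`term_url_template` must contain the placeholder {id}",
         call. = FALSE)
  }
  if (!grepl("{pmid}", pubmed_url_template, fixed = TRUE)) {
    stop("`pubmed_url_template` must contain the placeholder {pmid}",
         call. = FALSE)
  }
  assert_count(seed, "seed", positive = FALSE)
  structure(
    list(suggestion_limit = as.integer(suggestion_limit),
         field_weights = field_weights[needed],
         stopwords = tolower(stopwords),
         heatmap_cap = as.integer(heatmap_cap),
         dwell_threshold_s = as.numeric(dwell_threshold_s),
         combo_word_limit = as.integer(combo_word_limit),
         term_url_template = term_url_template,
         pubmed_url_template = pubmed_url_template,
         seed = as.integer(seed)),
    class = "triage_config")
}

#' @export
print.triage_config <- function(x, ...) {
  cat("<triage_config>\n")
  cat("  suggestion_limit:", x$suggestion_limit, "\n")
  cat("  field_weights:",
      paste(names(x$field_weights), x$field_weights, sep = "=",
            collapse = " "), "\n")
  cat("  stopwords:", length(x$stopwords), "words\n")
  cat("  heatmap_cap:", x$heatmap_cap, "\n")
  cat("  dwell_threshold_s:", x$dwell_threshold_s, "\n")
  cat("  combo_word_limit:", x$combo_word_limit, "\n")
  invisible(x)
}
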