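# The three-stage triage session state machine.
#
# Stage 1 "multiple_document": scan the ranked candidates via the
# query-result heatmap, dwell on rows (>= 5 s accumulated marks a document
# visited) and select documents into a pile. Stage 2 "individual_document":
# browse the selected-pile heatmap, inspect term-encoded abstracts, reject
# with the orange "x", and pick a document to read. Stage 3
# "further_reading": focus on one document (external PubMed entry). Users
# may retreat to any earlier stage at any time with all state preserved.

triage_stages <- function() {
  c("multiple_document", "individual_document", "further_reading")
}

#' Start a triage session
#'
#' Runs a conjunctive search for the pooled query words and seeds stage 1
#' with the ranked candidates (truncated to the heatmap display cap).
#'
#' @param index A `corpus_index`.
#' @param query_words Query words, or a `phenotype_selection` whose pooled
#'   words are used.
#' @param config A [triage_config()] (heatmap cap, dwell threshold).
#' @return Object of class `triage_session`.
#' @export
new_triage_session <- function(index, query_words,
                               config = triage_config()) {
  stopifnot(inherits(index, "corpus_index"))
  if (inherits(query_words, "phenotype_selection")) {
    query_words <- query_words$words
  }
  words <- unique(tokenize(query_words))
  if (!length(words)) stop("empty query", call. = FALSE)
  hits <- search_index(index, words, conjunctive = TRUE,
                       cap = config$heatmap_cap)
  structure(list(index = index,
                 query_words = words,
                 candidates = hits$pmid,
                 cursor = if (nrow(hits)) 1L else 0L,
                 dwell = stats::setNames(numeric(0), character(0)),
                 visited = integer(0),
                 selected_pile = integer(0),
                 reading = NA_integer_,
                 stage = "multiple_document",
                 dwell_threshold_s = config$dwell_threshold_s,
                 config = config),
            class = "triage_session")
}

#' @export
print.triage_session <- function(x, ...) {
  cat(sprintf(paste0(
    "<triage_session> stage %s | %d candidates | %d selected | ",
    "%d visited | cursor %d\n"),
    x$stage, length(x$candidates), length(x$selected_pile),
    length(x$visited), x$cursor))
  invisible(x)
}

working_set <- function(session) {
  if (session$stage == "multiple_document") session$candidates
  else session$selected_pile
}

#' Validate the invariants of a triage session
#'
#' Checks that the selected pile is a subset of the candidates, the reading
#' document (when set) is in the pile, every visited document has
#' accumulated dwell at or above the threshold, the stage is one of the
#' three triage stages and the cursor lies within the working set.
#'
#' @param session A `triage_session`.
#' @return Invisibly `TRUE`; errors describing the violated invariant
#'   otherwise.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "triage_session"))
  if (!session$stage %in% triage_stages()) {
    stop("invalid stage: ", session$stage, call. = FALSE)
  }
  if (!all(session$selected_pile %in% session$candidates)) {
    stop("selected_pile is not a subset of the candidates", call. = FALSE)
  }
  if (!is.na(session$reading) &&
      !session$reading %in% session$selected_pile) {
    stop("reading document is not in the selected pile", call. = FALSE)
  }
  if (!all(session$visited %in% as.integer(names(session$dwell)))) {
    stop("visited contains a document never dwelled on", call. = FALSE)
  }
  if (length(session$visited) &&
      any(session$dwell[as.character(session$visited)] <
          session$dwell_threshold_s)) {
    stop("visited contains a document below the dwell threshold",
         call. = FALSE)
  }
  ws <- working_set(session)
  if (length(ws)) {
    if (session$cursor < 1L || session$cursor > length(ws)) {
      stop("cursor out of range", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Accumulate dwell time on a document
#'
#' Dwell accumulates across repeat visits; the document joins the visited
#' set exactly when its accumulated dwell reaches the threshold (default
#' 5 s). The visited set only ever grows.
#'
#' @param session A `triage_session`.
#' @param pmid A candidate PMID.
#' @param seconds Non-negative dwell duration to add.
#' @return The updated session.
#' @export
record_dwell <- function(session, pmid, seconds) {
  stopifnot(inherits(session, "triage_session"))
  pmid <- as.integer(pmid)
  if (!pmid %in% session$candidates) {
    stop("unknown pmid: ", pmid, call. = FALSE)
  }
  if (!is.numeric(seconds) || length(seconds) != 1L || is.na(seconds) ||
      seconds < 0) {
    stop("`seconds` must be a non-negative number", call. = FALSE)
  }
  key <- as.character(pmid)
  session$dwell[key] <- (session$dwell[key] %||% 0)
  if (is.na(session$dwell[key])) session$dwell[key] <- 0
  session$dwell[key] <- session$dwell[key] + seconds
  if (session$dwell[key] >= session$dwell_threshold_s &&
      !pmid %in% session$visited) {
    session$visited <- c(session$visited, pmid)
  }
  session
}

#' Move the cursor through the current working set
#'
#' Arrow-key navigation: the cursor moves one row and clamps at the list
#' ends. The working set is the candidate list at stage 1 and the selected
#' pile at stages 2 and 3.
#'
#' @param session A `triage_session`.
#' @param direction `"next"` or `"prev"`.
#' @return The updated session.
#' @export
navigate <- function(session, direction = c("next", "prev")) {
  stopifnot(inherits(session, "triage_session"))
  direction <- match.arg(direction)
  ws <- working_set(session)
  if (!length(ws)) return(session)
  step <- if (direction == "next") 1L else -1L
  session$cursor <- min(max(session$cursor + step, 1L), length(ws))
  session
}

#' PMID under the cursor
#'
#' @param session A `triage_session`.
#' @return Integer PMID, or `NA` when the working set is empty.
#' @export
current_document <- function(session) {
  ws <- working_set(session)
  if (!length(ws) || session$cursor < 1L) return(NA_integer_)
  ws[session$cursor]
}

#' Add a candidate document to the selected pile
#'
#' Appends to the pile preserving selection order; selecting an already
#' selected document is a no-op (idempotent).
#'
#' @param session A `triage_session`.
#' @param pmid A candidate PMID.
#' @return The updated session.
#' @export
select_document <- function(session, pmid) {
  stopifnot(inherits(session, "triage_session"))
  pmid <- as.integer(pmid)
  if (!pmid %in% session$candidates) {
    stop("cannot select: pmid ", pmid, " is not a candidate", call. = FALSE)
  }
  if (!pmid %in% session$selected_pile) {
    session$selected_pile <- c(session$selected_pile, pmid)
  }
  session
}

#' Reject a document
#'
#' At stage 2 the orange "x" removes the document from the selected pile
#' (clearing the reading focus if it pointed there). At stage 1 there is no
#' explicit reject list -- a rejected candidate is simply never selected --
#' so rejecting a candidate leaves the session unchanged.
#'
#' @param session A `triage_session`.
#' @param pmid A PMID in the current working set.
#' @return The updated session.
#' @export
reject_document <- function(session, pmid) {
  stopifnot(inherits(session, "triage_session"))
  pmid <- as.integer(pmid)
  ws <- working_set(session)
  if (!pmid %in% ws) {
    stop("cannot reject: pmid ", pmid, " is not in the current working set",
         call. = FALSE)
  }
  if (session$stage == "multiple_document") return(session)
  session$selected_pile <- setdiff(session$selected_pile, pmid)
  if (!is.na(session$reading) && session$reading == pmid) {
    session$reading <- NA_integer_
  }
  if (length(session$selected_pile)) {
    session$cursor <- min(session$cursor, length(session$selected_pile))
  } else {
    session$cursor <- 0L
  }
  session
}

#' Set the reading focus
#'
#' @param session A `triage_session`.
#' @param pmid A PMID in the selected pile.
#' @return The updated session.
#' @export
read_document <- function(session, pmid) {
  stopifnot(inherits(session, "triage_session"))
  pmid <- as.integer(pmid)
  if (!pmid %in% session$selected_pile) {
    stop("cannot read: pmid ", pmid, " is not in the selected pile",
         call. = FALSE)
  }
  session$reading <- pmid
  session
}

#' Advance to the next triage stage
#'
#' `multiple_document -> individual_document` requires a non-empty selected
#' pile; `individual_document -> further_reading` requires a reading focus
#' (set with [read_document()]). The cursor resets to the top of the new
#' working set.
#'
#' @param session A `triage_session`.
#' @return The updated session.
#' @export
advance_stage <- function(session) {
  stopifnot(inherits(session, "triage_session"))
  if (session$stage == "multiple_document") {
    if (!length(session$selected_pile)) {
      stop("cannot advance: the selected pile is empty", call. = FALSE)
    }
    session$stage <- "individual_document"
    session$cursor <- 1L
  } else if (session$stage == "individual_document") {
    if (is.na(session$reading)) {
      stop("cannot advance: no reading document set", call. = FALSE)
    }
    session$stage <- "further_reading"
    session$cursor <- max(match(session$reading, session$selected_pile), 1L)
  } else {
    stop("already at the last stage", call. = FALSE)
  }
  session
}

#' Retreat to an earlier triage stage
#'
#' All state (pile, visited marks, dwell, reading focus) is preserved, so
#' the user can continue where they left off; each view dynamically
#' reflects the preserved state.
#'
#' @param session A `triage_session`.
#' @param to Target stage; defaults to the immediately preceding stage.
#' @return The updated session.
#' @export
retreat_stage <- function(session, to = NULL) {
  stopifnot(inherits(session, "triage_session"))
  stages <- triage_stages()
  pos <- match(session$stage, stages)
  if (is.null(to)) {
    if (pos == 1L) stop("already at the first stage", call. = FALSE)
    to <- stages[pos - 1L]
  }
  target <- match(to, stages)
  if (is.na(target) || target >= pos) {
    stop("can only retreat to an earlier stage", call. = FALSE)
  }
  session$stage <- stages[target]
  ws <- working_set(session)
  session$cursor <- if (length(ws)) min(max(session$cursor, 1L), length(ws))
                    else 0L
  session
}

#' Payload of the current stage
#'
#' Stage 1 emits the query-result heatmap over the candidates; stage 2 the
#' selected-pile heatmap plus the term-encoded abstract of the cursor
#' document; stage 3 the reading document's metadata, encoded abstract and
#' external PubMed URL. Column color indices are shared across stages.
#'
#' @param session A `triage_session`.
#' @return A named list payload (stage-dependent shape).
#' @export
stage_payload <- function(session) {
  stopifnot(inherits(session, "triage_session"))
  idx <- session$index
  words <- session$query_words
  hit_frame <- function(pmids) {
    data.frame(pmid = pmids,
               score = vapply(pmids, function(p)
                 score_document(idx, words, p), numeric(1)),
               rank = seq_along(pmids))
  }
  if (session$stage == "multiple_document") {
    hm <- build_heatmap(idx, hit_frame(session$candidates), words)
    list(stage = session$stage, heatmap = hm,
         visited = session$visited, cursor = session$cursor)
  } else if (session$stage == "individual_document") {
    hm <- build_heatmap(idx, hit_frame(session$selected_pile), words)
    cur <- current_document(session)
    cit <- if (!is.na(cur)) idx$citations[[as.character(cur)]] else NULL
    list(stage = session$stage, heatmap = hm, cursor = session$cursor,
         distribution = if (!is.null(cit)) term_distribution(cit, words),
         abstract_spans = if (!is.null(cit)) encode_abstract(cit, words))
  } else {
    cit <- idx$citations[[as.character(session$reading)]]
    list(stage = session$stage, pmid = session$reading,
         metadata = list(title = cit$title, journal = cit$journal,
                         year = cit$year, mesh_terms = cit$mesh_terms),
         abstract_spans = encode_abstract(cit, words),
         url = pubmed_url(session$reading,
                          session$config$pubmed_url_template))
  }
}

#' URL of a citation's PubMed entry
#'
#' @param pmid Positive integer PMID.
#' @param template URL template containing `{pmid}` exactly once.
#' @return The URL string.
#' @examples
#' pubmed_url(12345)
#' @export
pubmed_url <- function(pmid,
                       template = triage_config()$pubmed_url_template) {
  if (!is.numeric(pmid) || length(pmid) != 1L || is.na(pmid) || pmid < 1 ||
      pmid != floor(pmid)) {
    stop("`pmid` must be a positive integer", call. = FALSE)
  }
  assert_scalar_string(template, "template")
  n_ph <- length(gregexpr("{pmid}", template, fixed = TRUE)[[1]])
  if (!grepl("{pmid}", template, fixed = TRUE) || n_ph != 1L) {
    stop("`template` must contain the placeholder {pmid} exactly once",
         call. = FALSE)
  }
  sub("{pmid}", format(pmid, scientific = FALSE), template, fixed = TRUE)
}

#' Save a triage session as versioned JSON
#'
#' The index is not serialized; [load_triage_session()] re-attaches it.
#'
#' @param session A `triage_session`.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
save_triage_session <- function(session, path) {
  stopifnot(inherits(session, "triage_session"))
  state <- list(format = "phenotriage-session", format_version = 1L,
                query_words = session$query_words,
                candidates = session$candidates,
                cursor = session$cursor,
                dwell = as.list(session$dwell),
                visited = session$visited,
                selected_pile = session$selected_pile,
                reading = session$reading,
                stage = session$stage,
                dwell_threshold_s = session$dwell_threshold_s)
  jsonlite::write_json(state, path, auto_unbox = TRUE, na = "null",
                       digits = NA)
  invisible(path)
}

#' Load a triage session saved by [save_triage_session()]
#'
#' @param path File path.
#' @param index The `corpus_index` the session was built on.
#' @param config A [triage_config()].
#' @return A `triage_session`.
#' @export
load_triage_session <- function(path, index, config = triage_config()) {
  state <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(state$format, "phenotriage-session")) {
    stop("not a session file: ", path, call. = FALSE)
  }
  dwell <- unlist(state$dwell)
  if (is.null(dwell)) dwell <- stats::setNames(numeric(0), character(0))
  session <- structure(list(
    index = index,
    query_words = as.character(state$query_words),
    candidates = as.integer(state$candidates),
    cursor = as.integer(state$cursor),
    dwell = dwell,
    visited = as.integer(state$visited),
    selected_pile = as.integer(state$selected_pile),
    reading = if (is.null(state$reading) || is.na(state$reading))
      NA_integer_ else as.integer(state$reading),
    stage = state$stage,
    dwell_threshold_s = as.numeric(state$dwell_threshold_s),
    config = config), class = "triage_session")
  validate_session(session)
  session
}
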