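# Headless replay of the seven-step search-and-triage workflow: two
# vocabulary-building steps (term suggestion, sensitivity-encoded query
# selection) followed by five triaging steps across the three stages. An
# event script substitutes for the interactive browser front end so the
# full workflow is scriptable and deterministic.

#' Replay a search-and-triage event script
#'
#' Each event is a list with an `op` field and op-specific arguments:
#'
#' * `suggest` (`query`): emit ranked ontology suggestions.
#' * `select_phenotype` (`name`): add a phenotype to the selection.
#' * `expand`: emit the sensitivity-encoded combination table.
#' * `pick_combo` (`words`): use this word combination as the active query
#'   instead of the pooled selection words.
#' * `start_triage`: open a triage session on the active query.
#' * `navigate` (`direction`), `dwell` (`pmid`, `seconds`), `select`
#'   (`pmid`), `reject` (`pmid`), `read` (`pmid`), `advance`, `retreat`
#'   (`to`, optional): session verbs; `pmid` defaults to the cursor
#'   document where omitted.
#' * `payload`: emit the current stage payload.
#'
#' Replaying the same script against the same inputs is byte-deterministic
#' (see [workflow_payload_json()]). An event the state machine forbids
#' (e.g. advancing with an empty pile) raises an error naming the violated
#' invariant; the session invariants are re-validated after every event.
#'
#' @param corpus_index A `corpus_index`.
#' @param events List of event lists; an empty list yields no payloads.
#' @param suggester Optional `suggester_index` (required by `suggest`
#'   events).
#' @param config A [triage_config()].
#' @return List with `payloads` (one entry per emitting event, each tagged
#'   with `event` number and `op`) and the final `session` (or `NULL`).
#' @export
run_workflow <- function(corpus_index, events, suggester = NULL,
                         config = triage_config()) {
  stopifnot(inherits(corpus_index, "corpus_index"), is.list(events))
  phenotypes <- character(0)
  active_words <- NULL
  session <- NULL
  payloads <- list()
  emit <- function(i, op, body) {
    payloads[[length(payloads) + 1L]] <<- c(list(event = i, op = op), body)
  }
  need_session <- function(op) {
    if (is.null(session)) {
      stop("event '", op, "' before start_triage", call. = FALSE)
    }
  }
  pmid_arg <- function(ev) {
    if (!is.null(ev$pmid)) as.integer(ev$pmid) else current_document(session)
  }

  for (i in seq_along(events)) {
    ev <- events[[i]]
    op <- ev$op %||% stop("event ", i, " has no `op`", call. = FALSE)
    if (op == "suggest") {
      if (is.null(suggester)) {
        stop("suggest event requires a suggester index", call. = FALSE)
      }
      sugg <- suggest(suggester, ev$query, limit = ev$limit %||% NULL,
                      config = config)
      sugg$matched_fields <- vapply(sugg$matched_fields, paste,
                                    character(1), collapse = ",")
      emit(i, op, list(query = ev$query, suggestions = sugg))
    } else if (op == "select_phenotype") {
      phenotypes <- c(phenotypes, ev$name)
      active_words <- NULL  # new selection resets any picked combo
      emit(i, op, list(selection = phenotypes))
    } else if (op == "expand") {
      if (!length(phenotypes)) {
        stop("expand before any select_phenotype", call. = FALSE)
      }
      tab <- expansion_table(corpus_index, phenotypes, config = config)
      emit(i, op, list(table = tab))
    } else if (op == "pick_combo") {
      active_words <- unique(tokenize(ev$words))
      emit(i, op, list(words = active_words))
    } else if (op == "start_triage") {
      words <- active_words %||% {
        if (!length(phenotypes)) {
          stop("start_triage with no phenotypes selected", call. = FALSE)
        }
        phenotype_selection(phenotypes, stopwords = config$stopwords)$words
      }
      session <- new_triage_session(corpus_index, words, config = config)
      emit(i, op, list(n_candidates = length(session$candidates),
                       stage = session$stage))
    } else if (op == "navigate") {
      need_session(op)
      session <- navigate(session, ev$direction %||% "next")
    } else if (op == "dwell") {
      need_session(op)
      session <- record_dwell(session, pmid_arg(ev), ev$seconds)
    } else if (op == "select") {
      need_session(op)
      session <- select_document(session, pmid_arg(ev))
    } else if (op == "reject") {
      need_session(op)
      session <- reject_document(session, pmid_arg(ev))
    } else if (op == "read") {
      need_session(op)
      session <- read_document(session, pmid_arg(ev))
    } else if (op == "advance") {
      need_session(op)
      session <- advance_stage(session)
    } else if (op == "retreat") {
      need_session(op)
      session <- retreat_stage(session, to = ev$to %||% NULL)
    } else if (op == "payload") {
      need_session(op)
      emit(i, op, list(payload = stage_payload(session)))
    } else {
      stop("unknown event op: ", op, call. = FALSE)
    }
    if (!is.null(session)) validate_session(session)
  }
  list(payloads = payloads, session = session)
}

#' Serialize workflow payloads as canonical JSON
#'
#' A fixed serialization (sorted-key-free, full-precision numbers) used to
#' check that replaying an event script is byte-deterministic.
#'
#' @param result Return value of [run_workflow()].
#' @return A single JSON string.
#' @export
workflow_payload_json <- function(result) {
  strip <- function(x) {
    if (inherits(x, "heatmap_matrix") || inherits(x, "term_distribution")) {
      x <- unclass(x)
    }
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  as.character(jsonlite::toJSON(strip(result$payloads), dataframe = "rows",
                                auto_unbox = TRUE, digits = NA,
                                na = "null"))
}
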