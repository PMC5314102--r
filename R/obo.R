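# OBO 1.2/1.4 flat-file reading and canonical writing.
#
# Only the tags the suggester indexes are modelled: id, name, def, synonym,
# comment, is_a, is_obsolete. Unknown tags are ignored by design (the format
# carries many bookkeeping tags irrelevant to retrieval).

obo_text_to_lines <- function(input) {
  if (inherits(input, "connection")) return(readLines(input, warn = FALSE))
  if (!is.character(input)) {
    stop("`input` must be a file path, a connection, or OBO text",
         call. = FALSE)
  }
  if (length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
      file.exists(input)) {
    return(readLines(input, warn = FALSE))
  }
  # split embedded newlines while preserving empty lines (strsplit("") is
  # character(0), which would shift line numbers in error messages)
  unlist(lapply(input, function(x) {
    if (grepl("\n", x, fixed = TRUE)) strsplit(x, "\n", fixed = TRUE)[[1]]
    else x
  }), use.names = FALSE)
}

# Strip the trailing " [xrefs]" block and surrounding quotes from a
# def:/synonym: value; unescape \" and \\ inside the quoted part.
obo_unquote <- function(value) {
  m <- regmatches(value, regexec('^"((?:[^"\\\\]|\\\\.)*)"', value))[[1]]
  if (length(m) < 2L) return(trimws(value))
  gsub("\\\\(.)", "\\1", m[2])
}

obo_escape <- function(text) {
  gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", text))
}

#' Parse an OBO flat-file ontology
#'
#' Reads `[Term]` stanzas from an OBO 1.2/1.4 file and returns them as an
#' ontology collection. Obsolete terms are retained and flagged (downstream,
#' the suggester skips them). Synonym scope qualifiers (EXACT, BROAD, ...)
#' and trailing xref lists are stripped to the bare synonym text; `is_a`
#' targets that are absent from the file are reported as dangling rather
#' than resolved.
#'
#' @param input Path to an `.obo` file, a connection, or OBO text (a single
#'   string or a character vector of lines).
#' @return An object of class `ontology_collection`: a list with `terms` (a
#'   named list of term records with fields `term_id`, `name`, `definition`,
#'   `synonyms`, `comment`, `parents`, `obsolete`) and `dangling` (parent ids
#'   referenced but not defined).
#' @examples
#' obo <- c("[Term]", "id: HP:0000001", "name: All")
#' parse_obo(obo)
#' @seealso [write_obo()] for the canonical round-trip writer.
#' @export
parse_obo <- function(input) {
  lines <- obo_text_to_lines(input)
  terms <- list()
  n <- length(lines)
  i <- 1L
  in_term <- FALSE
  stanza_start <- NA_integer_
  cur <- NULL

  flush_term <- function(cur, stanza_start) {
    if (is.null(cur)) return(invisible(NULL))
    if (is.null(cur$term_id) || !nzchar(cur$term_id)) {
      stop(sprintf("malformed [Term] stanza starting at line %d: missing id",
                   stanza_start), call. = FALSE)
    }
    if (!cur$obsolete && !nzchar(cur$name)) {
      stop(sprintf(
        "malformed [Term] stanza starting at line %d: non-obsolete term %s has no name",
        stanza_start, cur$term_id), call. = FALSE)
    }
    cur
  }

  new_term <- function() {
    list(term_id = NULL, name = "", definition = "", synonyms = character(0),
         comment = "", parents = character(0), obsolete = FALSE)
  }

  while (i <= n) {
    line <- trimws(lines[i])
    if (grepl("^\\[.*\\]$", line)) {
      if (in_term) {
        t <- flush_term(cur, stanza_start)
        terms[[t$term_id]] <- t
      }
      in_term <- identical(line, "[Term]")
      stanza_start <- i
      cur <- if (in_term) new_term() else NULL
    } else if (in_term && nzchar(line) && !startsWith(line, "!")) {
      sep <- regexpr(":", line, fixed = TRUE)
      if (sep > 0L) {
        tag <- substr(line, 1L, sep - 1L)
        value <- trimws(substr(line, sep + 1L, nchar(line)))
        # drop trailing inline comments on unquoted tags
        if (tag == "id") {
          cur$term_id <- value
        } else if (tag == "name") {
          cur$name <- value
        } else if (tag == "def") {
          cur$definition <- obo_unquote(value)
        } else if (tag == "synonym") {
          cur$synonyms <- c(cur$synonyms, obo_unquote(value))
        } else if (tag == "comment") {
          cur$comment <- value
        } else if (tag == "is_a") {
          cur$parents <- c(cur$parents,
                           trimws(sub("!.*$", "", value)))
        } else if (tag == "is_obsolete") {
          cur$obsolete <- identical(tolower(value), "true")
        }
        # all other tags: ignored, not an error
      }
    }
    i <- i + 1L
  }
  if (in_term) {
    t <- flush_term(cur, stanza_start)
    terms[[t$term_id]] <- t
  }

  ids <- names(terms)
  if (anyDuplicated(ids)) {
    stop("duplicate term id in OBO input: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  all_parents <- unique(unlist(lapply(terms, `[[`, "parents"),
                               use.names = FALSE))
  structure(list(terms = terms,
                 dangling = setdiff(all_parents, ids)),
            class = "ontology_collection")
}

#' Write an ontology collection as canonical OBO text
#'
#' The canonical writer emits exactly the fields the parser models, in a
#' fixed order, so that `parse_obo(write_obo(parse_obo(x)))` reproduces the
#' in-scope fields identically. Synonyms are written with the EXACT scope
#' (scopes are not preserved by the parser).
#'
#' @param collection An `ontology_collection`.
#' @param path Optional file path; when `NULL` the OBO text is returned as a
#'   character vector of lines.
#' @return Invisibly, the lines written (or the lines themselves when
#'   `path` is `NULL`).
#' @export
write_obo <- function(collection, path = NULL) {
  stopifnot(inherits(collection, "ontology_collection"))
  lines <- c("format-version: 1.2", "")
  for (t in collection$terms) {
    lines <- c(lines, "[Term]", paste0("id: ", t$term_id),
               if (nzchar(t$name)) paste0("name: ", t$name))
    if (nzchar(t$definition)) {
      lines <- c(lines, paste0('def: "', obo_escape(t$definition), '" []'))
    }
    for (s in t$synonyms) {
      lines <- c(lines, paste0('synonym: "', obo_escape(s), '" EXACT []'))
    }
    if (nzchar(t$comment)) lines <- c(lines, paste0("comment: ", t$comment))
    for (p in t$parents) lines <- c(lines, paste0("is_a: ", p))
    if (t$obsolete) lines <- c(lines, "is_obsolete: true")
    lines <- c(lines, "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @export
print.ontology_collection <- function(x, ...) {
  obs <- sum(vapply(x$terms, `[[`, logical(1), "obsolete"))
  cat(sprintf("<ontology_collection> %d terms (%d obsolete)\n",
              length(x$terms), obs))
  if (length(x$dangling)) {
    cat("  dangling parents:", paste(x$dangling, collapse = ", "), "\n")
  }
  invisible(x)
}
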