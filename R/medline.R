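# MEDLINE-style citation input/output.
#
# Two interchangeable formats: PubMed/MEDLINE XML (MedlineCitation records,
# parsed with xml2) and line-delimited JSON with keys pmid, title, abstract,
# journal, year, mesh_terms, authors.

#' Construct a citation record
#'
#' @param pmid Positive integer PubMed identifier.
#' @param title Article title; must be non-empty.
#' @param abstract Abstract text; `""` when the record has none.
#' @param journal Journal title.
#' @param year Publication year (integer; `NA` allowed).
#' @param mesh_terms Character vector of MeSH descriptor names.
#' @param authors Character vector of "Surname Initials" strings.
#' @return A list of class `citation`.
#' @export
citation_record <- function(pmid, title, abstract = "", journal = "",
                            year = NA_integer_,
                            mesh_terms = character(0),
                            authors = character(0)) {
  if (!is.numeric(pmid) || length(pmid) != 1L || is.na(pmid) || pmid < 1 ||
      pmid != floor(pmid)) {
    stop("`pmid` must be a positive integer", call. = FALSE)
  }
  assert_scalar_string(title, "title")
  if (!nzchar(title)) stop("`title` must be non-empty", call. = FALSE)
  structure(list(pmid = as.integer(pmid), title = title,
                 abstract = as.character(abstract %||% ""),
                 journal = as.character(journal %||% ""),
                 year = suppressWarnings(as.integer(year)),
                 mesh_terms = as.character(mesh_terms),
                 authors = as.character(authors)),
            class = "citation_record")
}

#' @export
print.citation_record <- function(x, ...) {
  cat(sprintf("<citation %d> %s (%s, %s)\n", x$pmid, x$title,
              if (nzchar(x$journal)) x$journal else "?",
              if (is.na(x$year)) "?" else x$year))
  invisible(x)
}

drop_duplicate_pmids <- function(citations) {
  pmids <- vapply(citations, `[[`, integer(1), "pmid")
  dup <- duplicated(pmids)
  if (any(dup)) {
    warning("dropping ", sum(dup), " citation(s) with duplicate PMID: ",
            paste(unique(pmids[dup]), collapse = ", "), call. = FALSE)
    citations <- citations[!dup]
  }
  citations
}

#' Read citations from PubMed/MEDLINE XML
#'
#' Extracts PMID, title, abstract (multiple AbstractText sections are
#' concatenated with single spaces), journal title, year (from PubDate/Year,
#' falling back to the first four-digit run of MedlineDate), MeSH descriptor
#' names and author surnames+initials. Records without a PMID are skipped
#' with a warning; a duplicate PMID keeps only the first occurrence.
#'
#' @param input Path to an XML file, an XML string, or an `xml2` document.
#' @return List of `citation` records.
#' @export
read_medline_xml <- function(input) {
  doc <- if (inherits(input, "xml_document")) input else xml2::read_xml(input)
  nodes <- xml2::xml_find_all(doc, ".//MedlineCitation")
  out <- list()
  skipped <- 0L
  for (node in nodes) {
    pmid_txt <- xml2::xml_text(xml2::xml_find_first(node, "./PMID"))
    pmid <- suppressWarnings(as.integer(pmid_txt))
    if (is.na(pmid)) {
      skipped <- skipped + 1L
      next
    }
    title <- xml2::xml_text(
      xml2::xml_find_first(node, ".//Article/ArticleTitle"))
    if (is.na(title) || !nzchar(title)) title <- paste("PMID", pmid)
    abs_nodes <- xml2::xml_find_all(node, ".//Abstract/AbstractText")
    abstract <- paste(xml2::xml_text(abs_nodes), collapse = " ")
    journal <- xml2::xml_text(
      xml2::xml_find_first(node, ".//Article/Journal/Title"))
    if (is.na(journal)) journal <- ""
    year <- xml2::xml_text(
      xml2::xml_find_first(node, ".//JournalIssue/PubDate/Year"))
    if (is.na(year)) {
      mdate <- xml2::xml_text(
        xml2::xml_find_first(node, ".//JournalIssue/PubDate/MedlineDate"))
      year <- if (!is.na(mdate)) regmatches(mdate,
        regexpr("[0-9]{4}", mdate)) else NA_character_
      if (!length(year)) year <- NA_character_
    }
    mesh <- xml2::xml_text(
      xml2::xml_find_all(node, ".//MeshHeadingList/MeshHeading/DescriptorName"))
    authors <- vapply(
      xml2::xml_find_all(node, ".//AuthorList/Author"),
      function(a) {
        last <- xml2::xml_text(xml2::xml_find_first(a, "./LastName"))
        init <- xml2::xml_text(xml2::xml_find_first(a, "./Initials"))
        trimws(paste(stats::na.omit(c(last, init)), collapse = " "))
      }, character(1))
    authors <- authors[nzchar(authors)]
    out[[length(out) + 1L]] <- citation_record(
      pmid = pmid, title = title, abstract = abstract, journal = journal,
      year = year, mesh_terms = mesh, authors = authors)
  }
  if (skipped > 0L) {
    warning("skipped ", skipped, " record(s) without a PMID", call. = FALSE)
  }
  drop_duplicate_pmids(out)
}

#' Read citations from line-delimited JSON
#'
#' One JSON object per line with keys `pmid`, `title`, `abstract`,
#' `journal`, `year`, `mesh_terms`, `authors`.
#'
#' @param path File path.
#' @return List of `citation` records (first occurrence kept on duplicate
#'   PMIDs).
#' @export
read_citations_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    citation_record(pmid = rec$pmid, title = rec$title,
                    abstract = rec$abstract %||% "",
                    journal = rec$journal %||% "",
                    year = rec$year %||% NA_integer_,
                    mesh_terms = unlist(rec$mesh_terms) %||% character(0),
                    authors = unlist(rec$authors) %||% character(0))
  })
  drop_duplicate_pmids(out)
}

#' Write citations as line-delimited JSON
#'
#' @param citations List of `citation` records.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_citations_jsonl <- function(citations, path) {
  lines <- vapply(citations, function(cit) {
    jsonlite::toJSON(
      list(pmid = cit$pmid, title = cit$title, abstract = cit$abstract,
           journal = cit$journal, year = cit$year,
           mesh_terms = cit$mesh_terms, authors = cit$authors),
      auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
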