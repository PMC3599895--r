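#' Curation configuration for guideline reconciliation
#'
#' Word lists controlling the automated reconciliation of annotation
#' guidelines: annotations are trimmed of leading articles and possessive
#' pronouns so that a corpus annotated under a span-extending guideline can
#' be pooled with one that excludes such words. The defaults are the
#' articles and possessives that typically begin clinical concept
#' annotations.
#'
#' @param articles Lowercase article list.
#' @param possessives Lowercase possessive-pronoun list.
#' @param case_insensitive Compare ignoring case (default `TRUE`).
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(articles = c("a", "the", "any", "some", "an", "this"),
                            possessives = c("his", "her"),
                            case_insensitive = TRUE) {
  stopifnot(length(articles) > 0L, length(possessives) > 0L)
  structure(list(articles = tolower(articles),
                 possessives = tolower(possessives),
                 case_insensitive = isTRUE(case_insensitive)),
            class = "curation_config")
}

#' Strip leading articles/possessives from one span
#'
#' While the span's first token is in the configured word lists and the span
#' still has at least two tokens, the start is advanced by one; the end is
#' untouched and a span is never emptied. The operation is idempotent and
#' only leading tokens are considered.
#'
#' @param span One-row concept data frame (or list with `line`, `start`,
#'   `end`, `type`).
#' @param doc The [annotated_doc()] the span belongs to.
#' @param config A [curation_config()].
#' @return The curated span as a one-row concept data frame with refreshed
#'   `surface`.
#' @export
curate_span <- function(span, doc, config = curation_config()) {
  stopifnot(inherits(doc, "annotated_doc"))
  span <- as_concept_frame(span)
  stopifnot(nrow(span) == 1L)
  stopwords <- c(config$articles, config$possessives)
  toks <- doc$lines[[span$line]]
  while (span$start < span$end) {
    first <- toks[span$start]
    if (config$case_insensitive) first <- tolower(first)
    if (first %in% stopwords) span$start <- span$start + 1L else break
  }
  span$surface <- span_surface(doc$lines, span)
  span
}

#' Curate every annotation of a corpus
#'
#' Applies [curate_span()] to all concepts of every document; duplicate
#' spans created by the trimming (two annotations collapsing onto the same
#' bounds) are deduplicated. The report counts annotations whose bounds
#' changed, as a fraction of all annotations.
#'
#' @param x A [corpus()].
#' @param config A [curation_config()].
#' @return A list with `corpus` (the curated [corpus()]) and `report`
#'   (class `curation_report`: `n_total`, `n_modified`, `fraction_modified`).
#' @export
curate_corpus <- function(x, config = curation_config()) {
  stopifnot(inherits(x, "clin_corpus"))
  n_total <- 0L; n_modified <- 0L
  docs <- lapply(x$documents, function(d) {
    con <- d$concepts
    n_total <<- n_total + nrow(con)
    if (nrow(con)) {
      for (i in seq_len(nrow(con))) {
        cur <- curate_span(con[i, ], d, config)
        if (cur$start != con$start[i]) n_modified <<- n_modified + 1L
        con[i, ] <- cur
      }
      con <- unique(con)
    }
    annotated_doc(d$doc_id, d$lines, con, d$report_type)
  })
  report <- structure(
    list(n_total = n_total, n_modified = n_modified,
         fraction_modified = if (n_total == 0L) 0 else n_modified / n_total),
    class = "curation_report")
  list(corpus = corpus(x$source_label, docs), report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report> ", x$n_modified, "/", x$n_total,
      sprintf(" annotations modified (%.1f%%)\n", 100 * x$fraction_modified),
      sep = "")
  invisible(x)
}
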