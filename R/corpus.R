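#' Annotated document and corpus containers
#'
#' An `annotated_doc` holds one clinical note as a list of tokenized lines
#' (one sentence per line) plus a data frame of gold concept spans. All
#' coordinates are 1-based: `line` indexes the line, `start`/`end` index
#' tokens within that line and `end` is inclusive. A span never crosses a
#' line. The on-disk standoff serialization (see [read_standoff()]) uses the
#' customary 1-based line / 0-based token convention; the translation happens
#' only at that boundary.
#'
#' @param doc_id Unique document identifier.
#' @param lines List of character vectors, one vector of tokens per line.
#' @param concepts Data frame with columns `line`, `start`, `end` (integers)
#'   and `type` (character). A `surface` column is (re)derived from the
#'   tokens. Defaults to no concepts.
#' @param report_type Optional report-type label carried as metadata.
#' @return An object of class `annotated_doc`.
#' @seealso [corpus()], [read_standoff()], [to_conll()]
#' @export
annotated_doc <- function(doc_id, lines, concepts = empty_concepts(),
                          report_type = NA_character_) {
  stopifnot(is_string(doc_id), is.list(lines))
  lines <- lapply(lines, as.character)
  for (ln in lines) {
    if (any(!nzchar(ln)) || any(grepl("[[:space:]]", ln)))
      stop2("tokens must be non-empty and contain no whitespace (doc ", doc_id, ")")
  }
  concepts <- as_concept_frame(concepts)
  n_line <- length(lines)
  if (nrow(concepts)) {
    bad <- concepts$line < 1L | concepts$line > n_line
    if (!any(bad)) {
      len <- lengths(lines)[concepts$line]
      bad <- concepts$start < 1L | concepts$end > len | concepts$start > concepts$end
    }
    if (any(bad))
      stop2("concept span out of bounds in doc ", doc_id, ": ",
            paste(utils::capture.output(print(concepts[bad, , drop = FALSE])),
                  collapse = "\n"))
    key <- with(concepts, paste(line, start, end, type))
    if (anyDuplicated(key))
      stop2("duplicate concept spans in doc ", doc_id, ": ",
            paste(unique(key[duplicated(key)]), collapse = "; "))
    concepts$surface <- span_surface(lines, concepts)
  }
  structure(list(doc_id = doc_id, lines = lines, concepts = concepts,
                 report_type = report_type),
            class = "annotated_doc")
}

empty_concepts <- function() {
  data.frame(line = integer(0), start = integer(0), end = integer(0),
              type = character(0), surface = character(0),
              stringsAsFactors = FALSE)
}

as_concept_frame <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (nrow(x) == 0L) return(empty_concepts())
  need <- c("line", "start", "end", "type")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop2("concepts lack columns: ", paste(miss, collapse = ", "))
  x$line <- as.integer(x$line); x$start <- as.integer(x$start)
  x$end <- as.integer(x$end);   x$type <- as.character(x$type)
  if (is.null(x$surface)) x$surface <- NA_character_
  rownames(x) <- NULL
  x[c("line", "start", "end", "type", "surface")]
}

span_surface <- function(lines, concepts) {
  vapply(seq_len(nrow(concepts)), function(i) {
    paste(lines[[concepts$line[i]]][concepts$start[i]:concepts$end[i]],
          collapse = " ")
  }, character(1))
}

# canonical concept ordering used by serialization
sort_concepts <- function(concepts) {
  if (nrow(concepts) == 0L) return(concepts)
  o <- order(concepts$line, concepts$start, concepts$end, concepts$type)
  out <- concepts[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.annotated_doc <- function(x, ...) {
  cat("<annotated_doc> ", x$doc_id, ": ", length(x$lines), " lines, ",
      sum(lengths(x$lines)), " tokens, ", nrow(x$concepts), " concepts",
      if (!is.na(x$report_type)) paste0(" [", x$report_type, "]"), "\n",
      sep = "")
  invisible(x)
}

#' Build a corpus from annotated documents
#'
#' @param source_label Corpus label, e.g. `"local"` or `"foreign"`.
#' @param documents List of [annotated_doc()] objects with unique `doc_id`s.
#' @return An object of class `clin_corpus`; documents are stored as a list
#'   named by `doc_id`.
#' @export
corpus <- function(source_label, documents) {
  stopifnot(is_string(source_label), is.list(documents))
  ok <- vapply(documents, inherits, logical(1), "annotated_doc")
  if (!all(ok)) stop2("all documents must be annotated_doc objects")
  ids <- vapply(documents, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids))
    stop2("duplicate doc_ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(documents) <- ids
  structure(list(source_label = source_label, documents = documents),
            class = "clin_corpus")
}

#' @export
print.clin_corpus <- function(x, ...) {
  cat("<clin_corpus> '", x$source_label, "': ", length(x$documents),
      " documents, ", sum(vapply(x$documents, function(d) sum(lengths(d$lines)),
                                 numeric(1))),
      " tokens, ", sum(vapply(x$documents, function(d) nrow(d$concepts),
                              numeric(1))),
      " concepts (density ", sprintf("%.3f", concept_density(x)), ")\n",
      sep = "")
  invisible(x)
}

#' @export
length.clin_corpus <- function(x) length(x$documents)

#' Fraction of tokens inside concept annotations
#'
#' Sum of concept span lengths divided by the total token count — the
#' token-level annotation density used to characterise a corpus (around 0.11
#' for typical medical-problem corpora).
#'
#' @param x An `annotated_doc` or `clin_corpus`.
#' @return A number in `[0, 1]` (0 for an empty corpus).
#' @export
concept_density <- function(x) {
  docs <- if (inherits(x, "clin_corpus")) x$documents else list(x)
  tok <- sum(vapply(docs, function(d) sum(lengths(d$lines)), numeric(1)))
  span <- sum(vapply(docs, function(d) {
    if (nrow(d$concepts) == 0L) 0 else sum(d$concepts$end - d$concepts$start + 1)
  }, numeric(1)))
  if (tok == 0) 0 else span / tok
}

#' Histogram of annotation lengths in tokens
#'
#' Counts concept annotations by their token length. Guidelines that extend
#' spans over leading articles or trailing prepositional phrases shift this
#' distribution towards longer annotations.
#'
#' @param x A `clin_corpus` (or single `annotated_doc`).
#' @return A data frame with columns `length` and `count`, one row per
#'   observed span length, sorted; zero rows for a corpus without concepts.
#' @export
annotation_length_histogram <- function(x) {
  docs <- if (inherits(x, "clin_corpus")) x$documents else list(x)
  lens <- unlist(lapply(docs, function(d) {
    if (nrow(d$concepts)) d$concepts$end - d$concepts$start + 1L else integer(0)
  }), use.names = FALSE)
  if (length(lens) == 0L)
    return(data.frame(length = integer(0), count = integer(0)))
  tab <- table(lens)
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}
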