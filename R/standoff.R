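#' Read an i2b2-style standoff document
#'
#' The text file holds one tokenized sentence per line; the annotation file
#' holds one record per concept in the dialect
#' `c="<surface>" L:S L:E||t="<type>"` where `L` is a 1-based line number and
#' `S`/`E` are 0-based first/last token offsets on that line. Internally the
#' package uses 1-based token indices; conversion happens here.
#'
#' Malformed records and records whose coordinates do not resolve inside the
#' tokenized text are rejected with a diagnostic [warning()] naming the
#' document and the record; the remaining records are kept. The `surface`
#' field is re-derived from the tokens, with a warning when it differs from
#' the recorded surface.
#'
#' @param text_file Path to the note text.
#' @param annotation_file Path to the concept records.
#' @param doc_id Document identifier; defaults to the text file name without
#'   extension.
#' @param report_type Optional report-type metadata label.
#' @return An [annotated_doc()].
#' @export
read_standoff <- function(text_file, annotation_file,
                          doc_id = sub("\\.[^.]*$", "", basename(text_file)),
                          report_type = NA_character_) {
  raw <- readLines(text_file, warn = FALSE, encoding = "UTF-8")
  lines <- lapply(raw, tokenize)
  ann <- readLines(annotation_file, warn = FALSE, encoding = "UTF-8")
  ann <- ann[nzchar(trimws(ann))]
  pat <- '^c="(.*)" ([0-9]+):([0-9]+) ([0-9]+):([0-9]+)\\|\\|t="(.*)"$'
  keep <- list()
  for (i in seq_along(ann)) {
    m <- regmatches(ann[i], regexec(pat, ann[i]))[[1]]
    if (length(m) == 0L) {
      warning("doc ", doc_id, ": malformed record at line ", i, ": ", ann[i],
              call. = FALSE)
      next
    }
    l1 <- as.integer(m[3]); s <- as.integer(m[4]) + 1L
    l2 <- as.integer(m[5]); e <- as.integer(m[6]) + 1L
    if (l1 != l2) {
      warning("doc ", doc_id, ": record spans lines ", l1, "-", l2,
              " (concepts must lie on one line), rejected: ", ann[i],
              call. = FALSE)
      next
    }
    if (l1 < 1L || l1 > length(lines) || s < 1L || s > e ||
        e > length(lines[[l1]])) {
      warning("doc ", doc_id, ": out-of-bounds coordinates, rejected: ",
              ann[i], call. = FALSE)
      next
    }
    derived <- paste(lines[[l1]][s:e], collapse = " ")
    if (derived != m[2])
      warning("doc ", doc_id, ": recorded surface \"", m[2],
              "\" differs from tokens \"", derived, "\"", call. = FALSE)
    keep[[length(keep) + 1L]] <-
      data.frame(line = l1, start = s, end = e, type = m[7],
                 surface = derived, stringsAsFactors = FALSE)
  }
  concepts <- if (length(keep)) do.call(rbind, keep) else empty_concepts()
  annotated_doc(doc_id, lines, concepts, report_type)
}

#' Write an i2b2-style standoff document
#'
#' Inverse of [read_standoff()]: concepts are serialized sorted by
#' `(line, start, end, type)` with 1-based lines and 0-based token offsets,
#' so `read_standoff(write_standoff(d)) == d`.
#'
#' @param doc An [annotated_doc()].
#' @param text_file,annotation_file Output paths.
#' @return Invisibly, a character vector of the annotation records written.
#' @export
write_standoff <- function(doc, text_file, annotation_file) {
  stopifnot(inherits(doc, "annotated_doc"))
  writeLines(vapply(doc$lines, paste, character(1), collapse = " "),
             text_file, useBytes = TRUE)
  writeLines(standoff_records(doc), annotation_file, useBytes = TRUE)
  invisible(standoff_records(doc))
}

standoff_records <- function(doc) {
  con <- sort_concepts(doc$concepts)
  if (nrow(con) == 0L) return(character(0))
  sprintf('c="%s" %d:%d %d:%d||t="%s"', con$surface,
          con$line, con$start - 1L, con$line, con$end - 1L, con$type)
}

#' Read a directory of standoff documents as a corpus
#'
#' Pairs every `*.txt` file with the `*.con` file of the same stem.
#'
#' @param dir Directory containing `.txt`/`.con` pairs.
#' @param source_label Corpus label.
#' @return A [corpus()].
#' @export
read_corpus_dir <- function(dir, source_label) {
  txt <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(txt) == 0L) stop2("no .txt files in ", dir)
  docs <- lapply(txt, function(tf) {
    cf <- sub("\\.txt$", ".con", tf)
    if (!file.exists(cf)) stop2("missing annotation file for ", tf)
    read_standoff(tf, cf)
  })
  corpus(source_label, docs)
}

#' Write a corpus as standoff document pairs
#'
#' @param x A [corpus()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the document ids written.
#' @export
write_corpus_dir <- function(x, dir) {
  stopifnot(inherits(x, "clin_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in x$documents)
    write_standoff(d, file.path(dir, paste0(d$doc_id, ".txt")),
                   file.path(dir, paste0(d$doc_id, ".con")))
  invisible(names(x$documents))
}
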