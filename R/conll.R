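#' Convert a document to CoNLL-style BIO lines
#'
#' One `token<TAB>label` row per token, a blank line between sentences.
#' Labels are `B`/`I`/`O` for the selected concept type; concepts of that
#' type must be non-overlapping.
#'
#' @param doc An [annotated_doc()].
#' @param type Concept type to encode (default `"problem"`).
#' @return Character vector of CoNLL lines (including separating blanks).
#' @export
to_conll <- function(doc, type = "problem") {
  labs <- bio_encode(doc, type)
  out <- character(0)
  for (i in seq_along(doc$lines)) {
    out <- c(out, paste(doc$lines[[i]], labs[[i]], sep = "\t"))
    if (i < length(doc$lines)) out <- c(out, "")
  }
  out
}

#' Parse CoNLL-style BIO lines into a document
#'
#' Strict parser: an `I` label at sentence start or after `O` is an error
#' (unlike the tolerant [bio_decode()] used for model output).
#'
#' @param lines Character vector as produced by [to_conll()].
#' @param doc_id Document id for the result.
#' @param type Concept type to assign to decoded spans.
#' @param report_type Optional metadata label.
#' @return An [annotated_doc()] such that
#'   `from_conll(to_conll(d)) == d` for single-type documents.
#' @export
from_conll <- function(lines, doc_id = "doc", type = "problem",
                       report_type = NA_character_) {
  doc_lines <- list()
  concepts <- list()
  toks <- character(0); labs <- character(0)
  flush <- function() {
    if (length(toks) == 0L) return()
    li <- length(doc_lines) + 1L
    doc_lines[[li]] <<- toks
    spans <- bio_decode(labs, li, type, strict = TRUE,
                        context = paste0("sentence ", li))
    if (nrow(spans)) concepts[[length(concepts) + 1L]] <<- spans
    toks <<- character(0); labs <<- character(0)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) { flush(); next }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[2] %in% c("B", "I", "O"))
      stop2("malformed CoNLL line ", i, ": ", ln)
    if (parts[2] == "I" && (length(labs) == 0L || labs[length(labs)] == "O"))
      stop2("I label without preceding B/I at line ", i)
    toks <- c(toks, parts[1]); labs <- c(labs, parts[2])
  }
  flush()
  con <- if (length(concepts)) do.call(rbind, concepts) else empty_concepts()
  annotated_doc(doc_id, doc_lines, con, report_type)
}
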