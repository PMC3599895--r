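#' BIO-encode a document's concept spans
#'
#' Produces one `B`/`I`/`O` label per token and line: the first token of each
#' concept of the selected type is `B`, the rest `I`, everything else `O`.
#' Adjacent spans restart at `B`. Overlapping spans of the selected type
#' cannot be encoded and raise an error naming the colliding spans.
#'
#' @param doc An [annotated_doc()].
#' @param type Concept type to encode.
#' @return A list of character vectors, one per line.
#' @export
bio_encode <- function(doc, type = "problem") {
  stopifnot(inherits(doc, "annotated_doc"))
  con <- doc$concepts[doc$concepts$type == type, , drop = FALSE]
  labs <- lapply(lengths(doc$lines), function(n) rep("O", n))
  if (nrow(con)) {
    con <- sort_concepts(con)
    for (i in seq_len(nrow(con))) {
      li <- con$line[i]; s <- con$start[i]; e <- con$end[i]
      if (any(labs[[li]][s:e] != "O"))
        stop2("overlapping '", type, "' concepts at line ", li,
              " tokens ", s, "-", e, " (", con$surface[i], ")")
      labs[[li]][s:e] <- c("B", rep("I", e - s))
    }
  }
  labs
}

#' Decode a BIO label sequence into concept spans
#'
#' Tolerant by default: an illegal `I` at position 1 or after `O` opens a new
#' span (the standard repair for sequence-model output). With
#' `strict = TRUE` the same situation is an error, as required when parsing
#' CoNLL files.
#'
#' @param labels Character vector over `{"B","I","O"}`.
#' @param line_index Line number the labels belong to.
#' @param type Concept type for the returned spans.
#' @param strict Error on illegal `I` instead of repairing.
#' @param context Extra text for the strict-mode error message.
#' @return A concept data frame (`line`, `start`, `end`, `type`, `surface`
#'   with `NA` surface — the caller fills it from the tokens).
#' @export
bio_decode <- function(labels, line_index, type = "problem", strict = FALSE,
                       context = "") {
  stopifnot(all(labels %in% c("B", "I", "O")))
  starts <- integer(0); ends <- integer(0)
  open <- NA_integer_
  for (t in seq_along(labels)) {
    lab <- labels[t]
    if (lab == "B" || (lab == "I" && is.na(open))) {
      if (lab == "I" && strict)
        stop2("I label without preceding B/I at token ", t,
              if (nzchar(context)) paste0(" (", context, ")"))
      if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, t - 1L) }
      open <- t
    } else if (lab == "O" && !is.na(open)) {
      starts <- c(starts, open); ends <- c(ends, t - 1L)
      open <- NA_integer_
    }
  }
  if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, length(labels)) }
  if (length(starts) == 0L) return(empty_concepts())
  data.frame(line = line_index, start = starts, end = ends, type = type,
             surface = NA_character_, stringsAsFactors = FALSE)
}
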