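#' Lexical normalization of a token
#'
#' Applies, in order: (1) lowercasing; (2) removal of punctuation characters
#' (Unicode category P); (3) mapping of Greek-block letters to the marker
#' `"g"`; (4) mapping of decimal digits to `"9"`; (5) replacement by the
#' base form from `lexicon` when the result is a key. The composite is
#' idempotent — every output is a fixed point of the pipeline — which is why
#' the Greek marker is the lowercase `"g"`: an uppercase marker could not
#' survive re-application of step (1). The marker is therefore ambiguous
#' with a genuine letter g; the conflation is deliberate and harmless for
#' matching. Pure-punctuation tokens normalize to the empty string.
#'
#' @param text Character vector of tokens.
#' @param lexicon Base-form lexicon: a named character vector mapping
#'   surface form to base form (both lowercase), or `NULL`. An absent key
#'   maps to itself.
#' @return Character vector of normalized tokens (possibly `""`).
#' @examples
#' normalize_token(c("Pain,", "B12"))            # "pain"  "b99"
#' normalize_token("Fevers", c(fevers = "fever")) # "fever"
#' @export
normalize_token <- function(text, lexicon = NULL) {
  x <- tolower(as.character(text))
  x <- gsub("\\p{P}", "", x, perl = TRUE)
  x <- gsub("[\u0370-\u03ff\u1f00-\u1fff]", "g", x, perl = TRUE)
  x <- gsub("\\p{Nd}", "9", x, perl = TRUE)
  if (length(lexicon)) {
    hit <- match(x, names(lexicon))
    x[!is.na(hit)] <- unname(lexicon[hit[!is.na(hit)]])
  }
  x
}

#' Read a base-form lexicon file
#'
#' Plain UTF-8 file of `surface<TAB>baseform` lines, both lowercase. Base
#' forms must be fixed points of [normalize_token()] (so that normalization
#' stays idempotent); entries violating this are rejected with an error.
#'
#' @param path File path.
#' @return Named character vector usable as the `lexicon` argument of
#'   [normalize_token()].
#' @export
read_base_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop2("malformed lexicon line ", bad[1], ": ", lines[bad[1]])
  lex <- stats::setNames(vapply(parts, `[`, character(1), 2L),
                         vapply(parts, `[`, character(1), 1L))
  if (anyDuplicated(names(lex)))
    stop2("duplicate lexicon keys: ",
          paste(unique(names(lex)[duplicated(names(lex))]), collapse = ", "))
  fp <- normalize_token(unname(lex), lex)
  if (any(fp != unname(lex)))
    stop2("lexicon base forms are not normalization fixed points: ",
          paste(unname(lex)[fp != unname(lex)], collapse = ", "))
  lex
}

#' Build a term dictionary for overlapping lookup
#'
#' Terms are tokenized with the shared [tokenize()] rule and normalized
#' per token with [normalize_token()]; tokens normalizing to the empty
#' string (pure punctuation) are dropped; duplicate normalized entries are
#' collapsed. The dictionary stands in for a clinical terminology such as a
#' UMLS-derived phrase list.
#'
#' @param terms Either a path to a UTF-8 file of `term<TAB>label` lines, or
#'   a data frame with columns `term` and `label`.
#' @param lexicon Base-form lexicon passed to [normalize_token()].
#' @return An object of class `term_dictionary` with fields `entries`
#'   (data frame `ngram`, `label`, `len`), `max_len` and the `lexicon` used.
#' @export
build_dictionary <- function(terms, lexicon = NULL) {
  if (is.character(terms)) {
    lines <- readLines(terms, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad))
      stop2("malformed term line ", bad[1], ": ", lines[bad[1]])
    terms <- data.frame(term = vapply(parts, `[`, character(1), 1L),
                        label = vapply(parts, `[`, character(1), 2L),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(terms))
  if (nrow(terms) == 0L) {
    entries <- data.frame(ngram = character(0), label = character(0),
                          len = integer(0), stringsAsFactors = FALSE)
    return(structure(list(entries = entries, max_len = 0L, lexicon = lexicon,
                          index = new.env(parent = emptyenv())),
                     class = "term_dictionary"))
  }
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    toks <- normalize_token(tokenize(terms$term[i]), lexicon)
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) return(NULL)
    data.frame(ngram = paste(toks, collapse = " "), label = terms$label[i],
               len = length(toks), stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(entries))
    return(build_dictionary(terms[0, , drop = FALSE], lexicon))
  entries <- unique(entries)
  entries <- entries[order(entries$ngram, entries$label), , drop = FALSE]
  rownames(entries) <- NULL
  index <- new.env(parent = emptyenv(), size = nrow(entries))
  for (i in seq_len(nrow(entries))) {
    key <- entries$ngram[i]
    assign(key, c(get0(key, envir = index), entries$label[i]), envir = index)
  }
  structure(list(entries = entries, max_len = max(entries$len),
                 lexicon = lexicon, index = index),
            class = "term_dictionary")
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat("<term_dictionary> ", nrow(x$entries), " normalized entries, max length ",
      x$max_len, " tokens\n", sep = "")
  invisible(x)
}

#' Exhaustive overlapping dictionary lookup
#'
#' Tags every phrase occurrence in the document, including nested and
#' overlapping ones: each contiguous within-line token window (of 1 to
#' `max_len` content tokens) whose normalized form is a dictionary entry is
#' reported. Windows range over tokens whose normalized form is non-empty;
#' punctuation tokens are transparent (skipped inside windows) but reported
#' spans use original token coordinates of the first and last content token.
#'
#' @param doc An [annotated_doc()].
#' @param dict A [build_dictionary()] result.
#' @param lexicon Base-form lexicon; defaults to the one stored in `dict`.
#' @return Data frame `line`, `start`, `end`, `label` sorted by
#'   `(line, start, end, label)`.
#' @export
lookup_all <- function(doc, dict, lexicon = dict$lexicon) {
  stopifnot(inherits(doc, "annotated_doc"), inherits(dict, "term_dictionary"))
  out <- list()
  if (dict$max_len > 0L) {
    for (li in seq_along(doc$lines)) {
      norm <- normalize_token(doc$lines[[li]], lexicon)
      pos <- which(nzchar(norm))         # content-token positions
      nt <- norm[pos]
      n <- length(pos)
      for (i in seq_len(n)) {
        key <- ""
        for (len in seq_len(min(dict$max_len, n - i + 1L))) {
          key <- if (len == 1L) nt[i] else paste(key, nt[i + len - 1L])
          labels <- get0(key, envir = dict$index)
          for (lab in labels)
            out[[length(out) + 1L]] <-
              c(line = li, start = pos[i], end = pos[i + len - 1L], lab)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(line = integer(0), start = integer(0), end = integer(0),
                      label = character(0), stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  res <- data.frame(line = as.integer(m[, 1]), start = as.integer(m[, 2]),
                    end = as.integer(m[, 3]), label = m[, 4],
                    stringsAsFactors = FALSE)
  res <- res[order(res$line, res$start, res$end, res$label), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Dictionary-only baseline tagger
#'
#' Reduces [lookup_all()] matches of one semantic label to a set of
#' non-overlapping spans by repeatedly taking the longest remaining match
#' (ties broken by leftmost start) — the natural rule-based baseline against
#' which the learned tagger is compared.
#'
#' @param doc An [annotated_doc()].
#' @param dict A [build_dictionary()] result.
#' @param label Semantic label to keep (default `"problem"`).
#' @param lexicon Base-form lexicon; defaults to the dictionary's.
#' @return Concept data frame (`line`, `start`, `end`, `type`, `surface`).
#' @export
dictionary_baseline <- function(doc, dict, label = "problem",
                                lexicon = dict$lexicon) {
  m <- lookup_all(doc, dict, lexicon)
  m <- m[m$label == label, , drop = FALSE]
  if (nrow(m) == 0L) return(empty_concepts())
  m$len <- m$end - m$start + 1L
  m <- m[order(-m$len, m$line, m$start), , drop = FALSE]
  taken <- lapply(lengths(doc$lines), function(n) logical(n))
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    idx <- m$start[i]:m$end[i]
    if (!any(taken[[m$line[i]]][idx])) {
      keep[i] <- TRUE
      taken[[m$line[i]]][idx] <- TRUE
    }
  }
  m <- m[keep, , drop = FALSE]
  con <- data.frame(line = m$line, start = m$start, end = m$end, type = label,
                    surface = NA_character_, stringsAsFactors = FALSE)
  con <- sort_concepts(con)
  con$surface <- span_surface(doc$lines, con)
  con
}
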