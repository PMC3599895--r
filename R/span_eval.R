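#' Pair predicted and gold spans under a match mode
#'
#' Computes a maximum one-to-one pairing between predicted and gold concept
#' spans: under `"exact"` two spans match when line, start and end all agree;
#' under `"overlap"` when they lie on the same line and their token ranges
#' intersect. Each span is used at most once; the pairing is maximal
#' (augmenting-path bipartite matching), so `tp` is the largest achievable
#' number of pairs. `fp` are unpaired predictions and `fn` unpaired gold
#' spans.
#'
#' @param predicted,gold Concept data frames (columns `line`, `start`,
#'   `end`) belonging to the same document.
#' @param mode `"exact"` or `"overlap"`.
#' @return A list of class `match_result`: `mode`, `tp`, `fp`, `fn`.
#' @export
pair_spans <- function(predicted, gold, mode = c("exact", "overlap")) {
  mode <- match.arg(mode)
  p <- as_concept_frame(predicted); g <- as_concept_frame(gold)
  np <- nrow(p); ng <- nrow(g)
  if (np && ng) {
    ok <- matrix(FALSE, np, ng)
    for (i in seq_len(np)) {
      same_line <- g$line == p$line[i]
      ok[i, ] <- if (mode == "exact") {
        same_line & g$start == p$start[i] & g$end == p$end[i]
      } else {
        same_line & g$start <= p$end[i] & g$end >= p$start[i]
      }
    }
    tp <- max_bipartite_matching(ok)
  } else tp <- 0L
  structure(list(mode = mode, tp = tp, fp = np - tp, fn = ng - tp),
            class = "match_result")
}

# Kuhn's augmenting-path maximum bipartite matching on a logical
# adjacency matrix (rows: predicted, cols: gold). Returns the matching size.
max_bipartite_matching <- function(ok) {
  nr <- nrow(ok); nc <- ncol(ok)
  match_col <- rep(0L, nc)   # col -> matched row, 0 = free
  size <- 0L
  for (r in seq_len(nr)) {
    res <- augment(r, ok, match_col, rep(FALSE, nc))
    if (res$found) { match_col <- res$match_col; size <- size + 1L }
  }
  size
}

# recursive augmenting path; n spans per document is small
augment <- function(r, ok, match_col, seen) {
  for (c in which(ok[r, ])) {
    if (!seen[c]) {
      seen[c] <- TRUE
      if (match_col[c] == 0L) {
        match_col[c] <- r
        return(list(found = TRUE, match_col = match_col, seen = seen))
      }
      res <- augment(match_col[c], ok, match_col, seen)
      seen <- res$seen
      if (res$found) {
        match_col <- res$match_col
        match_col[c] <- r
        return(list(found = TRUE, match_col = match_col, seen = seen))
      }
    }
  }
  list(found = FALSE, match_col = match_col, seen = seen)
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> mode=", x$mode, " tp=", x$tp, " fp=", x$fp,
      " fn=", x$fn, "\n", sep = "")
  invisible(x)
}

#' Precision, recall and F1 from match counts
#'
#' `Precision = tp / (tp + fp)`, `Recall = tp / (tp + fn)`,
#' `F1 = 2 * Recall * Precision / (Recall + Precision)`; any ratio with a
#' zero denominator is defined as 0.
#'
#' @param m A [pair_spans()] result, or any list with `tp`, `fp`, `fn`.
#' @return A list of class `prf`: `precision`, `recall`, `f1`.
#' @export
prf <- function(m) {
  tp <- m$tp; fp <- m$fp; fn <- m$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * r * p / (r + p)
  structure(list(precision = p, recall = r, f1 = f), class = "prf")
}

#' @export
print.prf <- function(x, ...) {
  cat(sprintf("P=%.3f R=%.3f F1=%.3f\n", x$precision, x$recall, x$f1))
  invisible(x)
}

#' Micro-averaged corpus evaluation in both modes
#'
#' Sums match counts over documents (micro-average) and derives
#' precision/recall/F1 for exact and overlap span matching.
#'
#' @param predictions,gold Named lists of concept data frames with identical
#'   name sets (one entry per document).
#' @return A list with elements `exact` and `overlap`, each a list of class
#'   `prf` that also carries `tp`, `fp`, `fn` as attributes `counts`.
#' @export
evaluate_corpus <- function(predictions, gold) {
  pn <- names(predictions) %||% character(0)
  gn <- names(gold) %||% character(0)
  if (!setequal(pn, gn) || length(pn) != length(predictions) ||
      length(gn) != length(gold))
    stop2("document sets differ; only in predictions: ",
          paste(setdiff(pn, gn), collapse = ", "),
          "; only in gold: ", paste(setdiff(gn, pn), collapse = ", "))
  out <- list()
  for (mode in c("exact", "overlap")) {
    tp <- fp <- fn <- 0L
    for (id in gn) {
      m <- pair_spans(predictions[[id]], gold[[id]], mode)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    res <- prf(list(tp = tp, fp = fp, fn = fn))
    attr(res, "counts") <- c(tp = tp, fp = fp, fn = fn)
    out[[mode]] <- res
  }
  out
}

#' Annotation-phrase overlap between two corpora
#'
#' Measures how often annotation surface phrases of a source corpus occur in
#' a target corpus, in three progressively looser modes: `"exact"` (the
#' phrase is in the target set); `"ignore_one_start_word"` (the phrase, or
#' the phrase minus its first token, equals a target phrase or a target
#' phrase minus its first token); `"ignore_one_word"` (same, deleting any
#' single token from either side). Deletions apply only to phrases of two or
#' more tokens. Comparison is case-insensitive on raw tokens; the source is
#' treated as a multiset (every annotation counts), the target as a set of
#' distinct phrases.
#'
#' @param source_phrases List of character vectors (token sequences), one
#'   per source annotation; must be non-empty.
#' @param target_phrases List of character vectors: the target phrase set.
#' @param mode One of `"exact"`, `"ignore_one_start_word"`,
#'   `"ignore_one_word"`.
#' @return A list of class `overlap_stats`: `mode`, `n_source`, `n_matched`,
#'   `fraction`.
#' @export
phrase_overlap <- function(source_phrases, target_phrases,
                           mode = c("exact", "ignore_one_start_word",
                                    "ignore_one_word")) {
  mode <- match.arg(mode)
  if (length(source_phrases) == 0L)
    stop2("empty source phrase set: overlap fraction undefined")
  src <- lapply(source_phrases, function(p) tolower(as.character(p)))
  tgt <- lapply(target_phrases, function(p) tolower(as.character(p)))
  tgt_variants <- unique(unlist(lapply(tgt, phrase_variants, mode = mode)))
  matched <- vapply(src, function(p) {
    any(phrase_variants(p, mode) %in% tgt_variants)
  }, logical(1))
  n <- length(src); k <- sum(matched)
  structure(list(mode = mode, n_source = n, n_matched = k, fraction = k / n),
            class = "overlap_stats")
}

# all comparison keys a phrase contributes under a mode
phrase_variants <- function(p, mode) {
  keys <- paste(p, collapse = " ")
  if (length(p) >= 2L) {
    if (mode == "ignore_one_start_word") {
      keys <- c(keys, paste(p[-1L], collapse = " "))
    } else if (mode == "ignore_one_word") {
      keys <- c(keys, vapply(seq_along(p), function(i)
        paste(p[-i], collapse = " "), character(1)))
    }
  }
  keys
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat("<overlap_stats> mode=", x$mode, ": ", x$n_matched, "/", x$n_source,
      sprintf(" (%.1f%%)\n", 100 * x$fraction), sep = "")
  invisible(x)
}

#' Concept surfaces of a corpus as token sequences
#'
#' Convenience extractor feeding [phrase_overlap()]: every concept
#' annotation's surface, split into tokens.
#'
#' @param x A [corpus()].
#' @param type Optional concept type filter.
#' @return A list of character vectors, one per annotation.
#' @export
corpus_phrases <- function(x, type = NULL) {
  stopifnot(inherits(x, "clin_corpus"))
  out <- list()
  for (d in x$documents) {
    con <- d$concepts
    if (!is.null(type)) con <- con[con$type == type, , drop = FALSE]
    for (i in seq_len(nrow(con)))
      out[[length(out) + 1L]] <- d$lines[[con$line[i]]][con$start[i]:con$end[i]]
  }
  out
}
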