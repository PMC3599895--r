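# Shared fixtures built in code.

# the running example sentence used throughout the span tests
example_doc <- function() {
  annotated_doc(
    "ex1",
    list(tokenize("The patient denies any abdominal pain"),
         tokenize("She reports chest pain and a cough today .")),
    data.frame(line = c(1L, 2L), start = c(5L, 3L), end = c(6L, 4L),
               type = "problem"))
}

# small deterministic corpus for I/O round-trip and fold tests
tiny_corpus <- function(n_docs = 6, seed = 42) {
  generate_corpus(config = synth_config(n_docs = n_docs, lines_per_doc = 6,
                                        seed = seed))
}

# concept frame shorthand: spans as (line, start, end) triples
spans <- function(...) {
  if (length(c(...)) == 0) {
    return(data.frame(line = integer(0), start = integer(0),
                      end = integer(0), type = character(0),
                      stringsAsFactors = FALSE))
  }
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(line = m[, 1], start = m[, 2], end = m[, 3], type = "problem",
             stringsAsFactors = FALSE)
}

# exhaustive maximum one-to-one matching oracle (all injective assignments,
# recursion over predicted spans) -- independent of the package's matcher
oracle_max_matching <- function(ok) {
  nr <- nrow(ok); nc <- ncol(ok)
  if (nr == 0 || nc == 0) return(0L)
  best <- 0L
  recurse <- function(r, used, count) {
    if (count + (nr - r + 1L) <= best) return()   # bound
    if (r > nr) { best <<- max(best, count); return() }
    recurse(r + 1L, used, count)                  # leave row r unmatched
    for (c in which(ok[r, ])) if (!used[c]) {
      used[c] <- TRUE
      recurse(r + 1L, used, count + 1L)
      used[c] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, nc), 0L)
  best
}

# brute-force dictionary lookup oracle: test every window of every length
oracle_lookup <- function(doc, dict, lexicon = dict$lexicon) {
  hits <- list()
  keys <- split(dict$entries$label, dict$entries$ngram)
  for (li in seq_along(doc$lines)) {
    norm <- normalize_token(doc$lines[[li]], lexicon)
    pos <- which(nzchar(norm))
    for (i in seq_along(pos)) for (j in i:length(pos)) {
      key <- paste(norm[pos[i:j]], collapse = " ")
      for (lab in keys[[key]])
        hits[[length(hits) + 1L]] <- data.frame(
          line = li, start = pos[i], end = pos[j], label = lab,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(line = integer(0), start = integer(0),
                      end = integer(0), label = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$line, out$start, out$end, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

sort_concepts_for_test <- function(con) {
  con <- con[order(con$line, con$start, con$end, con$type), , drop = FALSE]
  rownames(con) <- NULL
  con
}

# random concept frame on a single imaginary line of `n_tok` tokens
random_spans <- function(n, n_tok = 12) {
  if (n == 0) return(spans())
  s <- sample.int(n_tok, n, replace = TRUE)
  e <- pmin(n_tok, s + sample(0:3, n, replace = TRUE))
  out <- unique(data.frame(line = 1L, start = s, end = e, type = "problem",
                           stringsAsFactors = FALSE))
  out
}
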