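#' Word shape of a token
#'
#' Maps uppercase letters to `A`, lowercase to `a`, digits to `9` and
#' anything else to `-`; the compressed shape collapses runs of equal
#' characters.
#'
#' @param text Character vector of tokens.
#' @return List with character vectors `shape` and `compressed`.
#' @examples
#' word_shape("Hb12")  # shape "Aa99", compressed "Aa9"
#' @export
word_shape <- function(text) {
  x <- as.character(text)
  shape <- gsub("[[:upper:]]", "A", x)
  shape <- gsub("[[:lower:]]", "a", shape)
  shape <- gsub("[0-9]", "9", shape)
  shape <- gsub("[^Aa9]", "-", shape)
  compressed <- gsub("(.)\\1+", "\\1", shape)
  list(shape = shape, compressed = compressed)
}

#' Heuristic part-of-speech provider
#'
#' A deterministic fallback tagger built from a closed-class word list plus
#' suffix rules, defaulting to `NN`. It exists so the pipeline is
#' self-contained; any function mapping a token vector to an equal-length
#' tag vector (e.g. a wrapper around an external biomedical tagger) can be
#' supplied instead wherever a POS provider is accepted.
#'
#' @return A function `(character tokens) -> character tags`.
#' @export
simple_pos_tagger <- function() {
  closed <- c(
    the = "DT", a = "DT", an = "DT", any = "DT", some = "DT", this = "DT",
    that = "DT", these = "DT", those = "DT", no = "DT",
    his = "PRP$", her = "PRP$", their = "PRP$", its = "PRP$", my = "PRP$",
    he = "PRP", she = "PRP", it = "PRP", they = "PRP", patient = "NN",
    i = "PRP", we = "PRP", you = "PRP",
    "in" = "IN", of = "IN", on = "IN", at = "IN", "for" = "IN", with = "IN",
    without = "IN", to = "TO", from = "IN", by = "IN", after = "IN",
    before = "IN", during = "IN", over = "IN", under = "IN", since = "IN",
    and = "CC", or = "CC", but = "CC", nor = "CC",
    is = "VBZ", are = "VBP", was = "VBD", were = "VBD", be = "VB",
    been = "VBN", has = "VBZ", have = "VBP", had = "VBD", will = "MD",
    would = "MD", can = "MD", could = "MD", may = "MD", should = "MD",
    not = "RB", very = "RB", also = "RB", still = "RB", now = "RB",
    there = "EX", as = "IN", "if" = "IN", than = "IN", per = "IN")
  function(tokens) {
    low <- tolower(tokens)
    tags <- unname(closed[low])
    need <- is.na(tags)
    w <- tokens[need]; lw <- low[need]
    t2 <- rep("NN", length(w))
    t2[grepl("^[[:punct:]]+$", w)] <- "PUNCT"
    t2[grepl("^[0-9][0-9.,:/-]*$", w)] <- "CD"
    t2[grepl("ing$", lw) & nchar(lw) > 4] <- "VBG"
    t2[grepl("ed$", lw) & nchar(lw) > 3] <- "VBD"
    t2[grepl("ly$", lw) & nchar(lw) > 3] <- "RB"
    plain <- t2 == "NN"
    t2[plain & grepl("s$", lw) & !grepl("ss$", lw) & nchar(lw) > 3] <- "NNS"
    t2[t2 %in% c("NN", "NNS") & grepl("^[[:upper:]]", w)] <- "NNP"
    tags[need] <- t2
    tags
  }
}

# Per-token dictionary-match state: B-<label>/I-<label> from the longest
# dictionary match covering the token (ties: leftmost start), else "O".
dict_bio_states <- function(n_tokens, matches) {
  state <- rep("O", n_tokens)
  if (is.null(matches) || nrow(matches) == 0L) return(state)
  best_len <- rep(-1L, n_tokens); best_start <- rep(.Machine$integer.max, n_tokens)
  best_lab <- rep(NA_character_, n_tokens); best_b <- rep(FALSE, n_tokens)
  for (i in seq_len(nrow(matches))) {
    s <- matches$start[i]; e <- matches$end[i]
    len <- e - s + 1L
    for (t in s:e) {
      if (len > best_len[t] || (len == best_len[t] && s < best_start[t])) {
        best_len[t] <- len; best_start[t] <- s
        best_lab[t] <- matches$label[i]; best_b[t] <- t == s
      }
    }
  }
  hit <- !is.na(best_lab)
  state[hit] <- paste0(ifelse(best_b[hit], "B-", "I-"), best_lab[hit])
  state
}

#' Extract token features for the sequence tagger
#'
#' For every token of a line, emits the feature families used by
#' feature-based clinical entity taggers — the word and its lowercased form,
#' prefixes and suffixes of length 1–4, word shape and compressed shape, a
#' digit indicator, the POS tag, and the dictionary-match state (B/I per
#' semantic label for the longest covering match, leftmost on ties) — for
#' the token itself and its neighbours at offsets -2..+2 (a five-token
#' window). Offsets beyond the line emit begin/end-of-line sentinel
#' features. Extraction is pure: identical inputs give identical features.
#'
#' @param tokens Character vector: the tokens of one line.
#' @param dict_matches [lookup_all()] rows restricted to this line (or
#'   `NULL`).
#' @param pos_tags Character vector of POS tags, same length as `tokens`,
#'   or `NULL` to omit the POS family.
#' @param window Half-width of the feature window (default 2, i.e. a
#'   five-token window).
#' @param affix_max Maximum affix length (default 4).
#' @return A list with one character vector of `name=value` feature strings
#'   per token.
#' @export
extract_features <- function(tokens, dict_matches = NULL, pos_tags = NULL,
                             window = 2L, affix_max = 4L) {
  n <- length(tokens)
  if (!is.null(pos_tags) && length(pos_tags) != n)
    stop2("pos_tags length ", length(pos_tags), " != tokens length ", n)
  if (n == 0L) return(list())
  base <- token_feature_table(tokens, dict_matches, pos_tags, affix_max)
  out <- vector("list", n)
  for (t in seq_len(n)) {
    feats <- character(0)
    for (o in (-window):window) {
      s <- t + o
      tag <- paste0("[", o, "]")
      if (s < 1L) {
        feats <- c(feats, paste0("bnd", tag, "=BOS"))
      } else if (s > n) {
        feats <- c(feats, paste0("bnd", tag, "=EOS"))
      } else {
        feats <- c(feats, paste0(names(base), tag, "=",
                                 vapply(base, `[`, character(1), s)))
      }
    }
    out[[t]] <- feats
  }
  out
}

# One row of feature values per token (no window applied yet).
token_feature_table <- function(tokens, dict_matches, pos_tags, affix_max) {
  lw <- tolower(tokens)
  sh <- word_shape(tokens)
  base <- list(w = tokens, wl = lw, shape = sh$shape, cshape = sh$compressed,
               isdig = ifelse(grepl("^[0-9]+$", tokens), "T", "F"),
               dict = dict_bio_states(length(tokens), dict_matches))
  if (!is.null(pos_tags)) base$pos <- as.character(pos_tags)
  nc <- nchar(lw)
  for (k in seq_len(affix_max)) {
    base[[paste0("p", k)]] <- ifelse(nc >= k, substr(lw, 1L, k), "_")
    base[[paste0("s", k)]] <- ifelse(nc >= k, substr(lw, nc - k + 1L, nc), "_")
  }
  base
}
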