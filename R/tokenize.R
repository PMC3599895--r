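#' Tokenize one line of clinical text
#'
#' Splits a raw line into tokens by whitespace, then peels leading and
#' trailing punctuation characters off each chunk as separate single-character
#' tokens. Internal punctuation (hyphens in `chest-pain`, apostrophes, the dot
#' in `3.5`) is kept inside the token. The same tokenizer is used for corpus
#' reading, dictionary construction and the synthetic generator, so token
#' coordinates always agree across modules.
#'
#' @param raw_line A length-one character string (one sentence per line).
#' @return A character vector of tokens; an empty or all-whitespace line
#'   yields `character(0)`.
#' @examples
#' tokenize("The patient denies any abdominal pain")
#' tokenize("pain, fever.")
#' @export
tokenize <- function(raw_line) {
  stopifnot(is.character(raw_line), length(raw_line) == 1L)
  if (is.na(raw_line)) return(character(0))
  chunks <- strsplit(trimws(raw_line), "[[:space:]]+")[[1]]
  chunks <- chunks[nzchar(chunks)]
  if (length(chunks) == 0L) return(character(0))
  out <- vector("list", length(chunks))
  for (i in seq_along(chunks)) out[[i]] <- split_punct(chunks[i])
  unlist(out, use.names = FALSE)
}

# Peel leading/trailing punctuation characters off a whitespace-free chunk,
# each as its own token; keep interior punctuation attached.
split_punct <- function(chunk) {
  lead <- character(0)
  trail <- character(0)
  repeat {
    first <- substr(chunk, 1L, 1L)
    if (nchar(chunk) > 0L && grepl("^\\p{P}$", first, perl = TRUE)) {
      lead <- c(lead, first)
      chunk <- substr(chunk, 2L, nchar(chunk))
    } else break
  }
  repeat {
    n <- nchar(chunk)
    last <- substr(chunk, n, n)
    if (n > 0L && grepl("^\\p{P}$", last, perl = TRUE)) {
      trail <- c(last, trail)
      chunk <- substr(chunk, 1L, n - 1L)
    } else break
  }
  c(lead, if (nchar(chunk) > 0L) chunk, trail)
}
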