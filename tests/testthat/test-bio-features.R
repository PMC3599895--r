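test_that("BIO encoding follows the span layout", {
  d <- example_doc()
  labs <- bio_encode(d)
  expect_identical(labs[[1]], c("O", "O", "O", "O", "B", "I"))
  # adjacent spans restart at B
  d2 <- annotated_doc("x", list(letters[1:5]),
                      rbind(spans(1, 2, 2), spans(1, 3, 4)))
  expect_identical(bio_encode(d2)[[1]], c("O", "B", "B", "I", "O"))
  d3 <- annotated_doc("x", list(letters[1:3]))
  expect_identical(bio_encode(d3)[[1]], c("O", "O", "O"))
  bad <- annotated_doc("x", list(letters[1:4]),
                       rbind(spans(1, 1, 2), spans(1, 2, 3)))
  expect_error(bio_encode(bad), "overlapping")
})

test_that("BIO decoding round-trips and repairs illegal I tolerantly", {
  expect_equal(bio_decode(c("O", "O", "B", "I", "O"), 1)[c("start", "end")],
               data.frame(start = 3L, end = 4L))
  expect_equal(nrow(bio_decode(rep("O", 4), 1)), 0L)
  rep_ <- bio_decode(c("I", "O", "B"), 1)
  expect_equal(rep_$start, c(1L, 3L))
  expect_equal(rep_$end, c(1L, 3L))
  expect_error(bio_decode(c("I", "O"), 1, strict = TRUE), "I label")
  # encode -> decode identity on random non-overlapping span sets
  set.seed(5)
  for (i in 1:40) {
    n_tok <- sample(4:12, 1)
    starts <- sort(sample.int(n_tok, sample(0:3, 1)))
    keep <- c(TRUE, diff(starts) > 1)[seq_along(starts)]
    starts <- starts[keep]
    ends <- pmin(n_tok, starts + ifelse(diff(c(starts, n_tok + 2)) > 2, 1, 0))
    d <- annotated_doc("r", list(paste0("t", seq_len(n_tok))),
                       if (length(starts)) {
                         data.frame(line = 1L, start = starts, end = ends,
                                    type = "problem")
                       } else empty_concepts())
    dec <- bio_decode(bio_encode(d)[[1]], 1)
    expect_equal(dec[c("line", "start", "end")],
                 sort_concepts_for_test(d$concepts)[c("line", "start", "end")])
  }
})

test_that("word shapes map character classes and compress runs", {
  ws <- word_shape(c("Hb12", "pain", "x", "T-4"))
  expect_identical(ws$shape, c("Aa99", "aaaa", "a", "A-9"))
  expect_identical(ws$compressed, c("Aa9", "a", "a", "A-9"))
})

test_that("dictionary feature uses longest covering match, leftmost on ties", {
  m <- data.frame(line = 1L, start = c(1L, 2L, 2L), end = c(2L, 2L, 3L),
                  label = "problem", stringsAsFactors = FALSE)
  # token 2 covered by (1-2), (2-2), (2-3): longest are (1-2) and (2-3),
  # leftmost start wins -> inside the (1-2) match
  st <- clinpool:::dict_bio_states(3L, m)
  expect_identical(st, c("B-problem", "I-problem", "I-problem"))
  expect_identical(clinpool:::dict_bio_states(2L, NULL), c("O", "O"))
})

test_that("feature windows carry neighbours and boundary sentinels", {
  toks <- c("chest", "pain", "today")
  fx <- extract_features(toks, NULL, c("NN", "NN", "RB"))
  expect_true("bnd[-1]=BOS" %in% fx[[1]])
  expect_true("bnd[-2]=BOS" %in% fx[[1]])
  expect_true("bnd[1]=EOS" %in% fx[[3]])
  expect_true("w[0]=chest" %in% fx[[1]])
  expect_true("w[1]=pain" %in% fx[[1]])
  expect_true("w[-1]=chest" %in% fx[[2]])
  expect_true("pos[0]=RB" %in% fx[[3]])
  expect_true("s2[0]=in" %in% fx[[2]])
  expect_true("shape[0]=aaaa" %in% fx[[2]])
  # purity: identical inputs give identical features
  expect_identical(fx, extract_features(toks, NULL, c("NN", "NN", "RB")))
  expect_error(extract_features(toks, NULL, c("NN", "NN")), "length")
})

test_that("dictionary-match feature reflects covering matches", {
  m <- data.frame(line = 1L, start = 1L, end = 2L, label = "problem",
                  stringsAsFactors = FALSE)
  fx <- extract_features(c("chest", "pain"), m, NULL)
  expect_true("dict[0]=B-problem" %in% fx[[1]])
  expect_true("dict[0]=I-problem" %in% fx[[2]])
  expect_true("dict[1]=I-problem" %in% fx[[1]])
  fx2 <- extract_features(c("chest", "pain"), NULL, NULL)
  expect_true("dict[0]=O" %in% fx2[[1]])
})

test_that("the fallback POS provider is deterministic and total", {
  pos <- simple_pos_tagger()
  toks <- c("The", "patient", "denies", "worsening", "pain", ",", "12",
            "quickly", "his", "symptoms")
  tags <- pos(toks)
  expect_equal(length(tags), length(toks))
  expect_identical(tags, pos(toks))
  expect_identical(tags[1], "DT")
  expect_identical(tags[6], "PUNCT")
  expect_identical(tags[7], "CD")
  expect_identical(tags[8], "RB")
  expect_identical(tags[9], "PRP$")
})
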