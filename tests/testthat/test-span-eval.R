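test_that("pair_spans counts exact and overlap matches one-to-one", {
  pred <- spans(1, 2, 3,  1, 6, 7)
  gold <- spans(1, 2, 3,  1, 5, 7)
  ex <- pair_spans(pred, gold, "exact")
  expect_equal(ex[c("tp", "fp", "fn")], list(tp = 1L, fp = 1L, fn = 1L))
  ov <- pair_spans(pred, gold, "overlap")
  expect_equal(ov[c("tp", "fp", "fn")], list(tp = 2L, fp = 0L, fn = 0L))
  # identity
  id <- pair_spans(gold, gold, "exact")
  expect_equal(id$fp + id$fn, 0L)
  # empty predictions
  e <- pair_spans(spans(), gold, "overlap")
  expect_equal(e[c("tp", "fn")], list(tp = 0L, fn = 2L))
  # spans on different lines never overlap
  expect_equal(pair_spans(spans(1, 1, 2), spans(2, 1, 2), "overlap")$tp, 0L)
})

test_that("one-to-one pairing: a prediction cannot match two golds", {
  pred <- spans(1, 1, 10)           # one long prediction over two golds
  gold <- spans(1, 1, 2,  1, 5, 6)
  ov <- pair_spans(pred, gold, "overlap")
  expect_equal(ov[c("tp", "fp", "fn")], list(tp = 1L, fp = 0L, fn = 1L))
})

test_that("pairing attains the exhaustive maximum on random small instances", {
  set.seed(71)
  for (i in 1:150) {
    pred <- random_spans(sample(0:6, 1))
    gold <- random_spans(sample(0:6, 1))
    for (mode in c("exact", "overlap")) {
      m <- pair_spans(pred, gold, mode)
      ok <- matrix(FALSE, nrow(pred), nrow(gold))
      if (nrow(pred) && nrow(gold))
        for (a in seq_len(nrow(pred)))
          ok[a, ] <- if (mode == "exact") {
            gold$start == pred$start[a] & gold$end == pred$end[a]
          } else {
            gold$start <= pred$end[a] & gold$end >= pred$start[a]
          }
      expect_equal(m$tp, oracle_max_matching(ok))
      expect_equal(m$tp + m$fp, nrow(pred))
      expect_equal(m$tp + m$fn, nrow(gold))
    }
  }
})

test_that("precision/recall/F1 formulas and zero conventions", {
  p <- prf(list(tp = 1, fp = 1, fn = 1))
  expect_equal(unclass(p), list(precision = 0.5, recall = 0.5, f1 = 0.5))
  z <- prf(list(tp = 0, fp = 0, fn = 5))
  expect_equal(unclass(z), list(precision = 0, recall = 0, f1 = 0))
  q <- prf(list(tp = 3, fp = 1, fn = 0))
  expect_equal(q$precision, 0.75)
  expect_equal(q$recall, 1)
  expect_equal(q$f1, 2 * 0.75 * 1 / 1.75)
})

test_that("evaluate_corpus pools counts before forming ratios", {
  pred <- list(a = spans(1, 1, 1, 1, 3, 3), b = spans(1, 1, 1, 1, 3, 3))
  gold <- list(a = spans(1, 1, 1, 1, 5, 5), b = spans(1, 1, 1, 1, 3, 3))
  # doc a: tp=1 fp=1 fn=1; doc b: tp=2 -> pooled tp=3 fp=1 fn=1
  ev <- evaluate_corpus(pred, gold)
  expect_equal(ev$exact$precision, 0.75)
  expect_equal(ev$exact$recall, 0.75)
  expect_equal(unname(attr(ev$exact, "counts")), c(3L, 1L, 1L))
  # single-document corpus equals pair_spans + prf
  one <- evaluate_corpus(pred["a"], gold["a"])
  expect_equal(one$exact,
               prf(pair_spans(pred$a, gold$a, "exact")),
               ignore_attr = TRUE)
  # all-empty predictions give zero recall in both modes
  none <- evaluate_corpus(list(a = spans(), b = spans()), gold)
  expect_equal(none$exact$recall, 0)
  expect_equal(none$overlap$recall, 0)
  expect_error(evaluate_corpus(pred, gold["a"]), "differ")
})

test_that("phrase overlap modes loosen matching progressively", {
  src <- list(c("severe", "cough"))
  tgt <- list(c("the", "severe", "cough"))
  expect_equal(phrase_overlap(src, tgt, "exact")$fraction, 0)
  expect_equal(phrase_overlap(src, tgt, "ignore_one_start_word")$fraction, 1)
  # subset source always matches fully, all modes
  s2 <- list(c("chest", "pain"), "fever")
  for (m in c("exact", "ignore_one_start_word", "ignore_one_word"))
    expect_equal(phrase_overlap(s2, c(s2, list("cough")), m)$fraction, 1)
  # interior deletion only matches in ignore_one_word mode
  s3 <- list(c("chest", "wall", "pain"))
  t3 <- list(c("chest", "pain"))
  expect_equal(phrase_overlap(s3, t3, "ignore_one_start_word")$fraction, 0)
  expect_equal(phrase_overlap(s3, t3, "ignore_one_word")$fraction, 1)
  # single-token phrases admit no deletion
  expect_equal(phrase_overlap(list("a"), list("b"), "ignore_one_word")$fraction, 0)
  expect_error(phrase_overlap(list(), t3), "empty source")
})

test_that("phrase overlap equals brute-force single-deletion enumeration", {
  set.seed(81)
  words <- c("a", "b", "c", "d")
  rand_phrases <- function(n) lapply(seq_len(n), function(i)
    sample(words, sample(1:3, 1), replace = TRUE))
  del_variants <- function(p, mode) {
    out <- list(p)
    if (length(p) >= 2) {
      if (mode == "ignore_one_start_word") out <- c(out, list(p[-1]))
      if (mode == "ignore_one_word")
        out <- c(out, lapply(seq_along(p), function(i) p[-i]))
    }
    vapply(out, paste, character(1), collapse = " ")
  }
  for (i in 1:60) {
    src <- rand_phrases(sample(1:6, 1)); tgt <- rand_phrases(sample(1:6, 1))
    for (mode in c("exact", "ignore_one_start_word", "ignore_one_word")) {
      expected <- sum(vapply(src, function(p) {
        any(vapply(tgt, function(q)
          any(del_variants(p, mode) %in% del_variants(q, mode)),
          logical(1)))
      }, logical(1)))
      expect_equal(phrase_overlap(src, tgt, mode)$n_matched, expected)
    }
  }
})

test_that("corpus_phrases extracts annotation surfaces as token sequences", {
  d <- example_doc()
  ph <- corpus_phrases(corpus("c", list(d)))
  expect_equal(ph, list(c("abdominal", "pain"), c("chest", "pain")))
})
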