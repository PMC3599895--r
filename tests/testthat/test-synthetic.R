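test_that("generation is deterministic: same seed, byte-identical corpora", {
  cfg <- synth_config(n_docs = 8, seed = 23)
  a <- generate_corpus(config = cfg)
  b <- generate_corpus(config = cfg)
  expect_identical(a, b)
  recs <- function(x) unlist(lapply(x$documents, function(d)
    c(vapply(d$lines, paste, character(1), collapse = " "),
      clinpool:::standoff_records(d))))
  expect_identical(recs(a), recs(b))
  c2 <- generate_corpus(config = synth_config(n_docs = 8, seed = 24))
  expect_false(identical(recs(a), recs(c2)))
})

test_that("zero-probability guideline yields bare spans at target density", {
  corp <- generate_corpus(config = synth_config(n_docs = 30, seed = 29))
  stop_words <- c(curation_config()$articles, curation_config()$possessives)
  firsts <- unlist(lapply(corp$documents, function(d)
    vapply(strsplit(d$concepts$surface, " "), `[`, character(1), 1L)))
  expect_false(any(firsts %in% stop_words))
  expect_lt(abs(concept_density(corp) - 0.11), 0.03)
})

test_that("realized density stays within tolerance across seeds", {
  dens <- vapply(1:20, function(s)
    concept_density(generate_corpus(config = synth_config(n_docs = 10,
                                                          seed = 300 + s))),
    numeric(1))
  expect_true(all(abs(dens - 0.11) < 0.03))
})

test_that("unreachable settings are rejected", {
  expect_error(generate_corpus(config = synth_config(density = 0.6,
                                                     n_docs = 2)),
               "density")
  expect_error(
    generate_corpus(profile = guideline_profile(p_article = 0.5),
                    config = synth_config(article_rate = 0.3)),
    "article_rate")
})

test_that("article-extension rate is recovered from the annotations", {
  stops <- curation_config()$articles
  frac <- vapply(1:5, function(s) {
    corp <- generate_corpus(profile = guideline_profile(p_article = 0.11),
                            config = synth_config(n_docs = 40,
                                                  seed = 400 + s))
    firsts <- unlist(lapply(corp$documents, function(d)
      vapply(strsplit(d$concepts$surface, " "), `[`, character(1), 1L)))
    mean(firsts %in% stops)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.11), 0.03)
})

test_that("gold span surfaces always agree with the document tokens", {
  corp <- generate_corpus(profile = profile_foreign(),
                          config = synth_config(n_docs = 10, seed = 37))
  for (d in corp$documents) {
    con <- d$concepts
    for (i in seq_len(nrow(con)))
      expect_identical(con$surface[i],
                       paste(d$lines[[con$line[i]]][con$start[i]:con$end[i]],
                             collapse = " "))
  }
})

test_that("article-including guideline lengthens annotations stochastically", {
  cfg <- synth_config(n_docs = 30, article_rate = 0.6, seed = 41)
  short <- generate_corpus(profile = guideline_profile(), config = cfg)
  long <- generate_corpus(profile = guideline_profile(p_article = 0.5),
                          config = cfg)
  mean_len <- function(x) {
    h <- annotation_length_histogram(x)
    sum(h$length * h$count) / sum(h$count)
  }
  expect_gt(mean_len(long), mean_len(short))
  expect_identical(annotation_length_histogram(long),
                   annotation_length_histogram(long))
  only2 <- annotated_doc("d", list(c("chest", "pain")), spans(1, 1, 2))
  h2 <- annotation_length_histogram(corpus("c", list(only2)))
  expect_equal(h2, data.frame(length = 2L, count = 1L))
})

test_that("paired corpora share vocabulary but not documents", {
  pair <- generate_paired_corpora(
    config_A = synth_config(n_docs = 25),
    config_B = synth_config(n_docs = 25), shared_seed = 43)
  expect_length(intersect(names(pair$local$documents),
                          names(pair$foreign$documents)), 0)
  # same-guideline pairing: phrase types from the shared vocabulary overlap
  same <- generate_paired_corpora(
    profile_A = guideline_profile(), profile_B = guideline_profile(),
    config_A = synth_config(n_docs = 100),
    config_B = synth_config(n_docs = 100), shared_seed = 47)
  ov <- phrase_overlap(corpus_phrases(same$local),
                       corpus_phrases(same$foreign), "exact")
  # bounded by realized type coverage of the target corpus (~0.9 here)
  expect_gt(ov$fraction, 0.8)
})

test_that("divergent article guidelines open a start-word overlap gap", {
  pair <- generate_paired_corpora(
    profile_A = guideline_profile(),
    profile_B = guideline_profile(p_article = 0.11),
    config_A = synth_config(n_docs = 30),
    config_B = synth_config(n_docs = 30), shared_seed = 53)
  src <- corpus_phrases(pair$foreign)
  tgt <- corpus_phrases(pair$local)
  exact <- phrase_overlap(src, tgt, "exact")$fraction
  loose <- phrase_overlap(src, tgt, "ignore_one_start_word")$fraction
  expect_gt(loose, exact)
})

test_that("vocabulary fraction bounds the cross-corpus exact phrase overlap", {
  prof <- guideline_profile(vocab_fraction = 0.5)
  pair <- generate_paired_corpora(
    profile_A = prof, profile_B = prof,
    config_A = synth_config(n_docs = 40),
    config_B = synth_config(n_docs = 40), shared_seed = 59)
  ov <- phrase_overlap(corpus_phrases(pair$local),
                       corpus_phrases(pair$foreign), "exact")
  # each side draws half the master lexicon independently: an annotation's
  # phrase is in the other side's vocabulary with probability ~0.5
  expect_lt(abs(ov$fraction - 0.5), 0.15)
})

test_that("report-type mixture labels documents", {
  corp <- generate_corpus(config = synth_config(
    n_docs = 40, seed = 61, report_types = c(note = 0.5, summary = 0.5)))
  types <- vapply(corp$documents, `[[`, character(1), "report_type")
  expect_setequal(unique(types), c("note", "summary"))
})
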