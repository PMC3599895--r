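# small corpora keep these design tests quick
exp_corpus <- function(n, seed, label = "local") {
  generate_corpus(config = synth_config(n_docs = n, lines_per_doc = 6,
                                        seed = seed), source_label = label)
}
fast_cfg <- tagger_config(maxit = 40)

test_that("fold plans are balanced, seeded and exhaustive", {
  corp <- exp_corpus(10, 211)
  plan <- make_folds(corp, k = 5, repeats = 2, seed = 3)
  for (a in plan$assignment) {
    expect_setequal(names(a), names(corp$documents))
    expect_true(all(table(a) == 2))
  }
  expect_identical(plan, make_folds(corp, k = 5, repeats = 2, seed = 3))
  expect_false(identical(plan$assignment,
                         make_folds(corp, 5, 2, seed = 4)$assignment))
  sizes <- table(make_folds(exp_corpus(11, 212), 5, 1, 1)$assignment[[1]])
  expect_setequal(as.integer(sizes), c(3L, 2L, 2L, 2L, 2L))
  expect_error(make_folds(exp_corpus(3, 213), k = 5), "at least")
})

test_that("cross-validation respects invariants and is reproducible", {
  corp <- exp_corpus(15, 221)
  dict <- concept_dictionary(fraction = 0.6, seed = 221)
  spec <- pooling_spec(corp)
  r1 <- run_cv(spec, config = fast_cfg, dictionary = dict, repeats = 1,
               seed = 5)
  r2 <- run_cv(spec, config = fast_cfg, dictionary = dict, repeats = 1,
               seed = 5)
  expect_identical(r1$cells, r2$cells)
  cells <- r1$cells
  expect_true(all(cells$f1 >= 0 & cells$f1 <= 1))
  # overlap-mode scores dominate exact-mode scores cell by cell
  wide <- merge(cells[cells$mode == "exact", ],
                cells[cells$mode == "overlap", ],
                by = c("rep", "fold"), suffixes = c("_e", "_o"))
  expect_true(all(wide$precision_o >= wide$precision_e - 1e-12))
  expect_true(all(wide$recall_o >= wide$recall_e - 1e-12))
  expect_true(all(wide$f1_o >= wide$f1_e - 1e-12))
  # summary means lie inside the per-cell range
  for (m in c("exact", "overlap")) {
    mm <- r1$summary$f1_mean[r1$summary$mode == m]
    expect_gte(mm, min(cells$f1[cells$mode == m]))
    expect_lte(mm, max(cells$f1[cells$mode == m]))
  }
})

test_that("pooling machinery guards against leakage and id collisions", {
  corp <- exp_corpus(10, 231)
  expect_error(pooling_spec(corp, corp), "share doc_ids")
  spec <- pooling_spec(exp_corpus(10, 231),
                       exp_corpus(5, 232, label = "foreign"),
                       subset_size = 20)
  expect_error(run_cv(spec, config = fast_cfg, repeats = 1),
               "subset_size")
})

test_that("supplementing a tiny local corpus with a compatible larger one helps", {
  pair <- generate_paired_corpora(
    profile_A = guideline_profile(), profile_B = guideline_profile(),
    config_A = synth_config(n_docs = 10, lines_per_doc = 6),
    config_B = synth_config(n_docs = 50, lines_per_doc = 6),
    shared_seed = 233)
  dict <- concept_dictionary(fraction = 0.6, seed = 233)
  better <- 0L
  for (r in 1:5) {
    plan <- make_folds(pair$local, k = 5, repeats = 1, seed = 240 + r)
    alone <- run_cv(pooling_spec(pair$local), plan, fast_cfg, dict)
    pooled <- run_cv(pooling_spec(pair$local, pair$foreign), plan, fast_cfg,
                     dict)
    f1 <- function(x) x$summary$f1_mean[x$summary$mode == "exact"]
    if (f1(pooled) >= f1(alone)) better <- better + 1L
  }
  expect_gte(better, 4L)
})

test_that("cross-corpus transfer degrades under divergent guidelines", {
  same <- generate_paired_corpora(
    profile_A = guideline_profile(), profile_B = guideline_profile(),
    config_A = synth_config(n_docs = 25, lines_per_doc = 6),
    config_B = synth_config(n_docs = 25, lines_per_doc = 6),
    shared_seed = 251)
  div <- generate_paired_corpora(
    profile_A = guideline_profile(),
    profile_B = guideline_profile(p_article = 0.5, p_possessive = 0.1,
                                  p_merge_prep = 0.9, vocab_fraction = 0.5),
    config_A = synth_config(n_docs = 25, lines_per_doc = 6,
                            article_rate = 0.6),
    config_B = synth_config(n_docs = 25, lines_per_doc = 6,
                            article_rate = 0.6),
    shared_seed = 251)
  dict <- concept_dictionary(fraction = 0.6, seed = 251)
  f1 <- function(x) x$summary$f1_mean[x$summary$mode == "exact"]
  tr_same <- run_cross_corpus(same$foreign, same$local, fast_cfg, dict)
  tr_div <- run_cross_corpus(div$foreign, div$local, fast_cfg, dict)
  expect_gt(f1(tr_same), f1(tr_div))
  expect_error(run_cross_corpus(same$local, same$local, fast_cfg, dict),
               "share doc_ids")
  self <- run_cross_corpus(same$local, same$local, fast_cfg, dict,
                           allow_identical = TRUE)
  expect_gte(f1(self), 0.9)
})
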