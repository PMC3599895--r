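#' Seeded repeated cross-validation fold plan
#'
#' Per repeat, documents are shuffled with a seed derived from `seed` and
#' assigned round-robin to `k` folds, so fold sizes differ by at most one
#' and the plan is fully reproducible.
#'
#' @param corpus A [corpus()] with at least `k` documents.
#' @param k Number of folds (default 5).
#' @param repeats Number of repeats (3 for full-corpus cross-validation,
#'   5 for subset learning curves).
#' @param seed Integer seed.
#' @return A list of class `fold_plan` with `k`, `repeats`, `seed` and
#'   `assignment` (one named fold-index vector per repeat).
#' @export
make_folds <- function(corpus, k = 5L, repeats = 3L, seed = 1L) {
  stopifnot(inherits(corpus, "clin_corpus"), k >= 2L, repeats >= 1L)
  ids <- names(corpus$documents)
  if (length(ids) < k)
    stop2("need at least k = ", k, " documents, have ", length(ids))
  assignment <- lapply(seq_len(repeats), function(r) {
    shuffled <- with_local_seed(derive_seed(seed, r, 1L), sample(ids))
    stats::setNames(rep_len(seq_len(k), length(ids)),
                    shuffled)[ids]
  })
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed), assignment = assignment),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan> k=", x$k, ", repeats=", x$repeats, ", ",
      length(x$assignment[[1]]), " documents, seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Pooled-training specification
#'
#' Names the local corpus whose folds are tested, an optional foreign corpus
#' added whole to every training set (never to a test fold), whether the
#' foreign annotations are curated first, and an optional truncation of the
#' local training fraction to `subset_size` documents.
#'
#' @param local Local [corpus()] (cross-validated).
#' @param foreign Optional foreign [corpus()] used only for training.
#' @param curate_foreign Apply [curate_corpus()] to the foreign corpus.
#' @param subset_size Optional number of local training documents sampled
#'   per fold.
#' @param curation [curation_config()] used when `curate_foreign` is set.
#' @return A list of class `pooling_spec`.
#' @export
pooling_spec <- function(local, foreign = NULL, curate_foreign = FALSE,
                         subset_size = NULL, curation = curation_config()) {
  stopifnot(inherits(local, "clin_corpus"),
            is.null(foreign) || inherits(foreign, "clin_corpus"))
  if (!is.null(foreign)) {
    shared <- intersect(names(local$documents), names(foreign$documents))
    if (length(shared))
      stop2("local and foreign corpora share doc_ids: ",
            paste(shared, collapse = ", "))
  }
  structure(list(local = local, foreign = foreign,
                 curate_foreign = isTRUE(curate_foreign),
                 subset_size = if (!is.null(subset_size))
                   as.integer(subset_size),
                 curation = curation),
            class = "pooling_spec")
}

# ---- shared experiment engine ----------------------------------------------

# Precompute encoded features and BIO labels for a set of documents under a
# single global feature index. Returns per-doc crf line records plus the
# gold concept frames used for evaluation.
compile_tagger_data <- function(docs, dictionary, lexicon, config, type,
                                extra_label_docs = NULL) {
  feat_strings <- lapply(docs, doc_feature_strings, dictionary = dictionary,
                         lexicon = lexicon, config = config)
  levels <- unique(unlist(feat_strings, use.names = FALSE))
  enc <- lapply(feat_strings, encode_feature_lines, levels = levels)
  records <- lapply(names(docs), function(id)
    crf_line_records(enc[[id]], doc_bio_ids(docs[[id]], type)))
  names(records) <- names(docs)
  extra <- NULL
  if (!is.null(extra_label_docs)) {
    # same text/features, alternative gold (e.g. curated annotations)
    extra <- lapply(names(extra_label_docs), function(id)
      crf_line_records(enc[[id]], doc_bio_ids(extra_label_docs[[id]], type)))
    names(extra) <- names(extra_label_docs)
  }
  list(levels = levels, records = records, extra_records = extra)
}

gold_of <- function(doc, type) {
  doc$concepts[doc$concepts$type == type, , drop = FALSE]
}

# Fit on the given line records, predict and evaluate the test documents.
fit_and_eval <- function(train_records, test_ids, docs, data, config, type) {
  lines <- do.call(c, unname(train_records))
  fit <- .crf_fit(lines, length(data$levels), config$lambda, config$maxit)
  preds <- lapply(test_ids, function(id) {
    ids <- crf_viterbi(data$records[[id]], fit$par, length(data$levels), 3L)
    decode_label_ids(docs[[id]], ids, type)
  })
  names(preds) <- test_ids
  gold <- lapply(docs[test_ids], gold_of, type = type)
  ev <- evaluate_corpus(preds, gold)
  check_mode_dominance(ev)
  ev
}

# overlap-mode scores can never fall below exact-mode scores; violated only
# by an implementation defect, so asserted on every run
check_mode_dominance <- function(ev) {
  for (m in c("precision", "recall", "f1"))
    if (ev$overlap[[m]] < ev$exact[[m]] - 1e-12)
      stop2("internal error: overlap-mode ", m, " below exact-mode")
  invisible(ev)
}

cell_row <- function(ev, ...) {
  do.call(rbind, lapply(c("exact", "overlap"), function(mode) {
    co <- attr(ev[[mode]], "counts")
    data.frame(..., mode = mode, tp = co[["tp"]], fp = co[["fp"]],
               fn = co[["fn"]], precision = ev[[mode]]$precision,
               recall = ev[[mode]]$recall, f1 = ev[[mode]]$f1,
               stringsAsFactors = FALSE)
  }))
}

summarise_cells <- function(cells, by) {
  agg <- function(stat)
    stats::aggregate(cells[c("precision", "recall", "f1")], cells[by], stat)
  m <- agg(mean); s <- agg(stats::sd)
  names(m)[names(m) %in% c("precision", "recall", "f1")] <-
    paste0(c("precision", "recall", "f1"), "_mean")
  names(s)[names(s) %in% c("precision", "recall", "f1")] <-
    paste0(c("precision", "recall", "f1"), "_sd")
  merge(m, s, by = by, sort = TRUE)
}

# ---- experiment designs ----------------------------------------------------

#' Cross-validation with optional foreign-corpus pooling
#'
#' For every repeat and fold, trains the tagger on the local documents
#' outside the test fold (optionally truncated to `subset_size`, sampled
#' with a derived seed) plus the entire — optionally curated — foreign
#' corpus, then evaluates on the test fold under exact and overlap span
#' matching. Test documents are guaranteed never to reach the training set.
#'
#' @param spec A [pooling_spec()].
#' @param plan A [make_folds()] plan for the local corpus, or `NULL` to
#'   build one from `k`, `repeats` and `seed`.
#' @param config A [tagger_config()].
#' @param dictionary,lexicon Terminology for dictionary features.
#' @param type Concept type.
#' @param k,repeats,seed Fold-plan parameters when `plan` is `NULL`; `seed`
#'   also drives subset sampling.
#' @return An `experiment_result`: list with `cells` (one row per
#'   repeat x fold x mode), `summary` (means and standard deviations per
#'   mode) and `provenance`.
#' @export
run_cv <- function(spec, plan = NULL, config = tagger_config(),
                   dictionary = NULL, lexicon = dictionary$lexicon,
                   type = "problem", k = 5L, repeats = 3L, seed = 1L) {
  stopifnot(inherits(spec, "pooling_spec"))
  if (is.null(plan)) plan <- make_folds(spec$local, k, repeats, seed)
  stopifnot(inherits(plan, "fold_plan"))

  foreign <- spec$foreign
  if (!is.null(foreign) && spec$curate_foreign)
    foreign <- curate_corpus(foreign, spec$curation)$corpus
  docs <- c(spec$local$documents,
            if (!is.null(foreign)) foreign$documents)
  data <- compile_tagger_data(docs, dictionary, lexicon, config, type)
  local_ids <- names(spec$local$documents)
  foreign_ids <- if (!is.null(foreign)) names(foreign$documents) else character(0)

  cells <- list()
  for (r in seq_len(plan$repeats)) {
    fold_of <- plan$assignment[[r]]
    for (f in seq_len(plan$k)) {
      test_ids <- names(fold_of)[fold_of == f]
      train_ids <- setdiff(local_ids, test_ids)
      if (!is.null(spec$subset_size)) {
        if (spec$subset_size > length(train_ids))
          stop2("subset_size ", spec$subset_size,
                " exceeds training-fold size ", length(train_ids))
        train_ids <- with_local_seed(derive_seed(plan$seed, r, f, 11L),
                                     sample(train_ids, spec$subset_size))
      }
      train_all <- c(train_ids, foreign_ids)
      if (length(intersect(test_ids, train_all)))
        stop2("leakage: test documents found in training set: ",
              paste(intersect(test_ids, train_all), collapse = ", "))
      ev <- fit_and_eval(data$records[train_all], test_ids, docs, data,
                         config, type)
      cells[[length(cells) + 1L]] <- cell_row(ev, rep = r, fold = f)
    }
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  structure(list(cells = cells, summary = summarise_cells(cells, "mode"),
                 provenance = list(design = "cv",
                                   local = spec$local$source_label,
                                   foreign = if (!is.null(spec$foreign))
                                     spec$foreign$source_label,
                                   curate_foreign = spec$curate_foreign,
                                   subset_size = spec$subset_size,
                                   k = plan$k, repeats = plan$repeats,
                                   seed = plan$seed, type = type)),
            class = "experiment_result")
}

#' Inter-corpus transfer evaluation
#'
#' Trains on one whole corpus and tests on another (disjoint) corpus —
#' the portability experiment. Training on the test corpus itself is a
#' sanity mode that must be requested explicitly.
#'
#' @param train,test [corpus()] objects with disjoint documents.
#' @param config,dictionary,lexicon,type As in [run_cv()].
#' @param allow_identical Permit `test` to share documents with `train`
#'   (near-ceiling sanity check only).
#' @return An `experiment_result` with a single cell per mode.
#' @export
run_cross_corpus <- function(train, test, config = tagger_config(),
                             dictionary = NULL, lexicon = dictionary$lexicon,
                             type = "problem", allow_identical = FALSE) {
  stopifnot(inherits(train, "clin_corpus"), inherits(test, "clin_corpus"))
  shared <- intersect(names(train$documents), names(test$documents))
  if (length(shared) && !allow_identical)
    stop2("train and test corpora share doc_ids: ",
          paste(shared, collapse = ", "))
  docs <- c(train$documents,
            test$documents[setdiff(names(test$documents),
                                   names(train$documents))])
  data <- compile_tagger_data(docs, dictionary, lexicon, config, type)
  ev <- fit_and_eval(data$records[names(train$documents)],
                     names(test$documents), docs, data, config, type)
  cells <- cell_row(ev, rep = 1L, fold = 1L)
  rownames(cells) <- NULL
  structure(list(cells = cells, summary = summarise_cells(cells, "mode"),
                 provenance = list(design = "cross",
                                   train = train$source_label,
                                   test = test$source_label, type = type)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> design=", x$provenance$design, "\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Learning curve over local-corpus subset sizes
#'
#' For every subset size, runs repeated k-fold cross-validation (default
#' 5 x 5-fold) with the local training fraction truncated to that many
#' documents, under three arms sharing the same local subsets: local-only,
#' local pooled with the whole foreign corpus, and local pooled with the
#' curated foreign corpus. This is the design that exposes whether pooling
#' helps only below a critical local corpus size.
#'
#' @param local,foreign [corpus()] objects (foreign added whole to training
#'   sets only).
#' @param subset_sizes Integer vector of local training-set sizes; each must
#'   be at most the training-fold size.
#' @param k,repeats Cross-validation shape (default 5 x 5).
#' @param curation [curation_config()] for the curated arm.
#' @param config,dictionary,lexicon,type As in [run_cv()].
#' @param seed Master seed for folds and subset sampling.
#' @return A `learning_curve` object: `cells` (size x arm x repeat x fold x
#'   mode), `summary` (means/sds per size x arm x mode) and `provenance`.
#' @seealso [find_pooling_crossing()]
#' @export
run_learning_curve <- function(local, foreign, subset_sizes, k = 5L,
                               repeats = 5L, curation = curation_config(),
                               config = tagger_config(), dictionary = NULL,
                               lexicon = dictionary$lexicon,
                               type = "problem", seed = 1L) {
  stopifnot(inherits(local, "clin_corpus"), inherits(foreign, "clin_corpus"),
            length(subset_sizes) >= 1L, all(subset_sizes >= 1L))
  subset_sizes <- sort(as.integer(subset_sizes))
  plan <- make_folds(local, k, repeats, seed)
  n_train_fold <- length(local$documents) -
    max(table(plan$assignment[[1]]))
  if (max(subset_sizes) > n_train_fold)
    stop2("largest subset size ", max(subset_sizes),
          " exceeds the training-fold size ", n_train_fold)

  curated <- curate_corpus(foreign, curation)$corpus
  docs <- c(local$documents, foreign$documents)
  data <- compile_tagger_data(docs, dictionary, lexicon, config, type,
                              extra_label_docs = curated$documents)
  local_ids <- names(local$documents)
  foreign_ids <- names(foreign$documents)
  arm_foreign <- list(local = NULL, pooled = data$records[foreign_ids],
                      pooled_curated = data$extra_records[foreign_ids])

  cells <- list()
  for (size in subset_sizes) {
    for (r in seq_len(plan$repeats)) {
      fold_of <- plan$assignment[[r]]
      for (f in seq_len(plan$k)) {
        test_ids <- names(fold_of)[fold_of == f]
        pool_ids <- setdiff(local_ids, test_ids)
        train_ids <- with_local_seed(derive_seed(seed, size, r, f),
                                     sample(pool_ids, size))
        if (length(intersect(test_ids, c(train_ids, foreign_ids))))
          stop2("leakage: test documents found in training set")
        for (arm in names(arm_foreign)) {
          recs <- c(data$records[train_ids], arm_foreign[[arm]])
          ev <- fit_and_eval(recs, test_ids, docs, data, config, type)
          cells[[length(cells) + 1L]] <-
            cell_row(ev, size = size, arm = arm, rep = r, fold = f)
        }
      }
    }
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  structure(list(cells = cells,
                 summary = summarise_cells(cells, c("size", "arm", "mode")),
                 provenance = list(design = "learning_curve",
                                   local = local$source_label,
                                   foreign = foreign$source_label,
                                   subset_sizes = subset_sizes, k = plan$k,
                                   repeats = plan$repeats, seed = seed,
                                   type = type)),
            class = c("learning_curve", "experiment_result"))
}

#' Detect the pooling benefit crossing in a learning curve
#'
#' Compares the pooled and local-only arms of a [run_learning_curve()]
#' result at each subset size. The characteristic pattern is a crossing:
#' pooling beats local-only training at the smallest size and falls below
#' it at the largest — pooling pays off only while the local corpus is
#' below a critical size.
#'
#' @param curve A `learning_curve` object.
#' @param arm Pooled arm to compare (`"pooled"` or `"pooled_curated"`).
#' @param mode Evaluation mode (default `"exact"`).
#' @param metric Score column (default `"f1"`).
#' @return A list: per-size mean scores for both arms (`sizes`, `local`,
#'   `pooled`, `gain`), and logicals `beneficial_at_smallest`,
#'   `harmful_at_largest`, `crossing`.
#' @export
find_pooling_crossing <- function(curve, arm = "pooled", mode = "exact",
                                  metric = "f1") {
  stopifnot(inherits(curve, "learning_curve"))
  s <- curve$summary
  col <- paste0(metric, "_mean")
  s <- s[s$mode == mode, , drop = FALSE]
  sizes <- sort(unique(s$size))
  loc <- s[match(paste(sizes, "local"), paste(s$size, s$arm)), col]
  poo <- s[match(paste(sizes, arm), paste(s$size, s$arm)), col]
  gain <- poo - loc
  list(sizes = sizes, local = loc, pooled = poo, gain = gain,
       beneficial_at_smallest = gain[1] >= 0,
       harmful_at_largest = gain[length(gain)] <= 0,
       crossing = gain[1] >= 0 && gain[length(gain)] <= 0)
}

#' @export
plot.learning_curve <- function(x, mode = "exact", metric = "f1", ...) {
  s <- x$summary[x$summary$mode == mode, , drop = FALSE]
  col <- paste0(metric, "_mean")
  sizes <- sort(unique(s$size))
  arms <- c("local", "pooled", "pooled_curated")
  y <- sapply(arms, function(a)
    s[match(paste(sizes, a), paste(s$size, s$arm)), col])
  graphics::matplot(sizes, y, type = "b", pch = 19, lty = 1:3,
                    col = c("black", "red3", "dodgerblue3"),
                    xlab = "local training documents",
                    ylab = paste(mode, metric), ...)
  graphics::legend("bottomright", legend = arms, lty = 1:3, pch = 19,
                   col = c("black", "red3", "dodgerblue3"), bty = "n")
  invisible(x)
}
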