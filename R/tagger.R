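#' Tagger configuration
#'
#' Bundles the feature and optimisation settings of the sequence tagger so
#' that a model always predicts with the configuration it was trained with.
#'
#' @param window Feature half-window; 2 gives the five-token window.
#' @param affix_max Maximum prefix/suffix length (default 4).
#' @param use_pos Include POS-tag features from `pos_tagger`.
#' @param pos_tagger A POS provider `(tokens) -> tags`; defaults to the
#'   built-in [simple_pos_tagger()].
#' @param lambda L2 regularisation strength on all weights.
#' @param maxit Maximum L-BFGS iterations.
#' @return A list of class `tagger_config`.
#' @export
tagger_config <- function(window = 2L, affix_max = 4L, use_pos = TRUE,
                          pos_tagger = simple_pos_tagger(), lambda = 1,
                          maxit = 100L) {
  stopifnot(window >= 0L, affix_max >= 0L, lambda >= 0, maxit >= 1L)
  structure(list(window = as.integer(window),
                 affix_max = as.integer(affix_max),
                 use_pos = isTRUE(use_pos), pos_tagger = pos_tagger,
                 lambda = lambda, maxit = as.integer(maxit)),
            class = "tagger_config")
}

# label coding shared by training and decoding
.bio_levels <- c("O", "B", "I")

# Feature strings for every line of a document (list of per-token character
# vectors per line). Purely a function of the document, dictionary, lexicon
# and config.
doc_feature_strings <- function(doc, dictionary, lexicon, config) {
  matches <- if (!is.null(dictionary)) lookup_all(doc, dictionary, lexicon)
  lapply(seq_along(doc$lines), function(li) {
    toks <- doc$lines[[li]]
    m <- if (!is.null(matches)) matches[matches$line == li, , drop = FALSE]
    pos <- if (config$use_pos && length(toks)) config$pos_tagger(toks)
    extract_features(toks, m, pos, config$window, config$affix_max)
  })
}

# Encode per-token feature-string vectors against a fixed feature level
# vector; features absent from the levels are dropped (they carry zero
# weight in any model trained on those levels).
encode_feature_lines <- function(line_feats, levels) {
  lapply(line_feats, function(tok_feats) {
    lapply(tok_feats, function(fs) {
      ids <- match(fs, levels)
      as.integer(ids[!is.na(ids)])
    })
  })
}

# integer BIO labels per line for one document
doc_bio_ids <- function(doc, type) {
  lapply(bio_encode(doc, type), function(l) match(l, .bio_levels))
}

# assemble crf line records from encoded features and label lists
crf_line_records <- function(enc_lines, lab_lines = NULL) {
  lapply(seq_along(enc_lines), function(i) {
    rec <- list(feats = enc_lines[[i]])
    rec$labels <- if (is.null(lab_lines)) {
      rep(1L, length(enc_lines[[i]]))
    } else lab_lines[[i]]
    rec
  })
}

.crf_fit <- function(lines, n_feat, lambda, maxit, n_lab = 3L) {
  npar <- n_lab + n_lab^2 + n_feat * n_lab
  cache <- new.env(parent = emptyenv())
  obj <- function(p) {
    if (is.null(cache$par) || !identical(p, cache$par)) {
      cache$res <- crf_nll_grad(lines, p, lambda, n_feat, n_lab)
      cache$par <- p
    }
    cache$res
  }
  fit <- stats::optim(numeric(npar), fn = function(p) obj(p)$nll,
                      gr = function(p) obj(p)$grad, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  list(par = fit$par, nll = fit$value, convergence = fit$convergence)
}

# decode viterbi label ids for one document into a concept frame
decode_label_ids <- function(doc, label_ids, type) {
  spans <- list()
  for (li in seq_along(label_ids)) {
    labs <- .bio_levels[label_ids[[li]]]
    sp <- bio_decode(labs, li, type)
    if (nrow(sp)) spans[[length(spans) + 1L]] <- sp
  }
  con <- if (length(spans)) do.call(rbind, spans) else empty_concepts()
  if (nrow(con)) con$surface <- span_surface(doc$lines, con)
  con
}

#' Fit a conditional random field concept tagger
#'
#' Trains a linear-chain CRF over BIO labels for one concept type, using the
#' feature set of [extract_features()] (lexical, affix, shape, POS and
#' dictionary-lookup features over a five-token window). Parameters are
#' estimated by L2-penalised maximum likelihood (forward-backward gradients,
#' L-BFGS); training is deterministic given the corpus, configuration and
#' seed.
#'
#' @param corpus A [corpus()] with gold annotations of `type`.
#' @param dictionary Optional [build_dictionary()] terminology used for
#'   dictionary-match features.
#' @param lexicon Base-form lexicon; defaults to the dictionary's.
#' @param type Concept type to learn (default `"problem"`).
#' @param config A [tagger_config()].
#' @param seed Integer recorded in the model metadata (the estimator itself
#'   has no stochastic step).
#' @return An object of class `crf_tagger` with components `weights`,
#'   `feat_levels`, `config`, `type`, `dictionary`, `lexicon`, `meta`,
#'   `nll` and `convergence`.
#' @seealso [predict.crf_tagger()], [dictionary_baseline()]
#' @examples
#' \donttest{
#' corp <- generate_corpus(config = synth_config(n_docs = 20, seed = 7))
#' dict <- concept_dictionary()
#' fit <- crf_tagger(corp, dict)
#' predict(fit, corp$documents[[1]])
#' }
#' @export
crf_tagger <- function(corpus, dictionary = NULL, lexicon = dictionary$lexicon,
                       type = "problem", config = tagger_config(), seed = 1L) {
  stopifnot(inherits(corpus, "clin_corpus"), inherits(config, "tagger_config"))
  if (length(corpus$documents) == 0L) stop2("empty corpus")
  n_con <- sum(vapply(corpus$documents,
                      function(d) sum(d$concepts$type == type), numeric(1)))
  if (n_con == 0L) stop2("corpus has no concepts of type '", type, "'")

  feat_strings <- lapply(corpus$documents, doc_feature_strings,
                         dictionary = dictionary, lexicon = lexicon,
                         config = config)
  levels <- unique(unlist(feat_strings, use.names = FALSE))
  enc <- lapply(feat_strings, encode_feature_lines, levels = levels)
  labs <- lapply(corpus$documents, doc_bio_ids, type = type)
  lines <- do.call(c, lapply(seq_along(enc), function(i)
    crf_line_records(enc[[i]], labs[[i]])))
  fit <- .crf_fit(lines, length(levels), config$lambda, config$maxit)

  structure(list(weights = fit$par, feat_levels = levels,
                 config = config, type = type, dictionary = dictionary,
                 lexicon = lexicon,
                 meta = list(corpus_label = corpus$source_label,
                             n_docs = length(corpus$documents),
                             n_concepts = n_con, seed = as.integer(seed)),
                 nll = fit$nll, convergence = fit$convergence),
            class = "crf_tagger")
}

#' Predict concept spans with a fitted tagger
#'
#' Runs Viterbi decoding over the model's feature configuration and decodes
#' the BIO output tolerantly into spans. Features never seen in training are
#' ignored; a document that is entirely out of vocabulary simply yields few
#' or no spans.
#'
#' @param object A [crf_tagger()] fit.
#' @param newdata An [annotated_doc()] or [corpus()].
#' @param ... Unused.
#' @return For a document, a concept data frame; for a corpus, a named list
#'   of concept data frames (one per document).
#' @export
predict.crf_tagger <- function(object, newdata, ...) {
  if (inherits(newdata, "clin_corpus"))
    return(lapply(newdata$documents, function(d) predict(object, d)))
  stopifnot(inherits(newdata, "annotated_doc"))
  fs <- doc_feature_strings(newdata, object$dictionary, object$lexicon,
                            object$config)
  enc <- encode_feature_lines(fs, object$feat_levels)
  ids <- crf_viterbi(crf_line_records(enc), object$weights,
                     length(object$feat_levels), 3L)
  decode_label_ids(newdata, ids, object$type)
}

#' @export
print.crf_tagger <- function(x, ...) {
  cat("<crf_tagger> for '", x$type, "' concepts\n",
      "  trained on: ", x$meta$corpus_label, " (", x$meta$n_docs, " docs, ",
      x$meta$n_concepts, " concepts)\n",
      "  features:   ", length(x$feat_levels), " (window ±",
      x$config$window, ", affixes 1-", x$config$affix_max,
      if (x$config$use_pos) ", POS", if (!is.null(x$dictionary)) ", dictionary",
      ")\n",
      "  penalised NLL: ", sprintf("%.2f", x$nll),
      " (lambda = ", x$config$lambda, ")\n", sep = "")
  invisible(x)
}

#' @export
coef.crf_tagger <- function(object, ...) {
  L <- 3L
  w <- object$weights
  emit <- matrix(w[-(1:(L + L * L))], ncol = L, byrow = TRUE,
                 dimnames = list(object$feat_levels, .bio_levels))
  structure(emit,
            init = stats::setNames(w[1:L], .bio_levels),
            trans = matrix(w[L + 1:(L * L)], L, L, byrow = TRUE,
                           dimnames = list(.bio_levels, .bio_levels)))
}

#' @export
summary.crf_tagger <- function(object, n = 10L, ...) {
  emit <- coef(object)
  score <- apply(abs(emit), 1, max)
  top <- emit[order(-score)[seq_len(min(n, nrow(emit)))], , drop = FALSE]
  out <- list(model = object, top_features = top,
              transitions = attr(emit, "trans"))
  class(out) <- "summary.crf_tagger"
  out
}

#' @export
print.summary.crf_tagger <- function(x, ...) {
  print(x$model)
  cat("\nTransition weights:\n")
  print(round(x$transitions, 3))
  cat("\nStrongest emission features:\n")
  print(round(x$top_features, 3))
  invisible(x)
}
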