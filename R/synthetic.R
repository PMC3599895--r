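#' Default concept lexicon for the synthetic generator
#'
#' A master vocabulary standing in for a clinical terminology: medical
#' "problem" phrases of 1-4 tokens (signs/symptoms and disorders), a filler
#' vocabulary of narrative words, body-part names for prepositional-phrase
#' templates, and sentence templates with concept slots. Concept phrases are
#' disjoint from the filler vocabulary so that gold spans are unambiguous.
#'
#' @return A list of class `concept_lexicon` with components `concepts`
#'   (character vector of space-joined phrases), `filler`, `body_parts` and
#'   `templates`.
#' @export
default_concept_lexicon <- function() {
  heads <- c("pain", "edema", "nausea", "fatigue", "dizziness", "cough",
             "fever", "rash", "weakness", "anemia", "hypertension",
             "diabetes", "pneumonia", "asthma", "arthritis", "migraine",
             "seizures", "anxiety", "depression", "insomnia", "bronchitis",
             "cellulitis", "gastritis", "neuropathy", "tachycardia",
             "bradycardia", "hypotension", "hyperlipidemia", "dyspnea",
             "vertigo", "pruritus", "dysphagia", "palpitations",
             "constipation", "diarrhea", "vomiting", "cyanosis", "jaundice",
             "syncope", "tremor", "hematuria", "dysuria", "cancer",
             "stroke", "sepsis", "gout", "emphysema", "osteoporosis")
  mods <- c("chest", "abdominal", "chronic", "acute", "severe", "lower",
            "back", "joint", "muscle", "intermittent", "bilateral",
            "persistent", "mild", "recurrent", "epigastric", "exertional")
  pair_heads <- c("pain", "edema", "weakness", "cough", "rash", "fatigue")
  pairs <- as.vector(outer(mods, pair_heads, paste))
  long <- c("shortness of breath", "loss of appetite", "blurred vision",
            "atrial fibrillation", "congestive heart failure",
            "deep vein thrombosis", "urinary tract infection",
            "upper respiratory infection", "chronic kidney disease",
            "acute renal failure", "coronary artery disease",
            "chronic obstructive pulmonary disease",
            "gastroesophageal reflux disease", "altered mental status")
  filler <- c("patient", "was", "seen", "today", "without", "noted", "on",
              "examination", "review", "of", "systems", "otherwise",
              "unremarkable", "continues", "medication", "follow", "up",
              "visit", "stable", "improved", "tolerating", "diet", "well",
              "ambulating", "discharge", "home", "plan", "continue",
              "current", "regimen", "labs", "within", "normal", "limits",
              "vital", "signs", "blood", "pressure", "heart", "rate",
              "temperature", "afebrile", "alert", "oriented", "states",
              "feels", "better", "since", "admission", "yesterday",
              "morning", "evening", "overnight", "week", "days", "overall",
              "condition", "remains", "appears", "comfortable", "resting",
              "family", "present", "discussed", "care", "goals", "will",
              "monitor", "closely", "repeat", "tomorrow", "interval",
              "changes", "reviewed", "records", "outside", "imaging",
              "pending", "results", "counseled", "at", "length")
  body_parts <- c("chest", "back", "abdomen", "neck", "shoulder", "knee",
                  "hip", "groin", "flank", "calf")
  tpl <- function(kind, ...) list(kind = kind, tokens = c(...))
  templates <- list(
    tpl("plain", "patient", "reports", "<P>", "today", "."),
    tpl("plain", "she", "denies", "<P>", "."),
    tpl("plain", "he", "describes", "<P>", "for", "several", "days", "."),
    tpl("plain", "exam", "notable", "for", "<P>", "."),
    tpl("plain", "history", "significant", "for", "<P>", "."),
    tpl("plain", "problems", "include", "<P>", ",", "<P>", "."),
    tpl("plain", "no", "evidence", "of", "<P>", "currently", "."),
    tpl("plain", "symptoms", "of", "<P>", "have", "resolved", "."),
    tpl("plain", "patient", "admitted", "with", "<P>", "last", "week", "."),
    tpl("plain", "treatment", "for", "<P>", "was", "initiated", "."),
    tpl("prep", "patient", "has", "<P>", "in", "the", "<B>", "."),
    tpl("prep", "complains", "of", "<P>", "in", "the", "<B>", "."),
    tpl("conj", "reports", "<P>", "and", "<P>", "this", "week", "."),
    tpl("conj", "exam", "shows", "<P>", "and", "<P>", "."),
    tpl("org", "seen", "in", "the", "<P>", "clinic", "today", "."),
    tpl("org", "referred", "to", "the", "<P>", "service", "."))
  concepts <- unique(c(heads, pairs, long))
  stopifnot(length(concepts) >= 100L,
            !any(concepts %in% filler))
  structure(list(concepts = concepts, filler = filler,
                 body_parts = body_parts, templates = templates),
            class = "concept_lexicon")
}

#' Annotation-guideline profile
#'
#' Parametric description of how a guideline turns concept mentions into
#' annotations: the marginal probability that an annotation is extended over
#' a preceding article (`p_article`) or possessive pronoun
#' (`p_possessive`); the probability that a concept mention inside an
#' organisation-name context (e.g. the disease name in "cancer clinic") is
#' annotated at all (`p_unrelated`); the probabilities that a
#' concept-plus-prepositional-phrase pattern (`p_merge_prep`) or a
#' conjunction list (`p_merge_conj`) is annotated as one merged span rather
#' than separate concept spans; and the fraction of the master concept
#' vocabulary this guideline's corpus draws from (`vocab_fraction`).
#'
#' @param p_article,p_possessive,p_unrelated,p_merge_prep,p_merge_conj,vocab_fraction
#'   Probabilities in `[0, 1]`.
#' @return A list of class `guideline_profile`.
#' @seealso [profile_local()], [profile_foreign()]
#' @export
guideline_profile <- function(p_article = 0, p_possessive = 0,
                              p_unrelated = 0, p_merge_prep = 0,
                              p_merge_conj = 0, vocab_fraction = 1) {
  p <- list(p_article = p_article, p_possessive = p_possessive,
            p_unrelated = p_unrelated, p_merge_prep = p_merge_prep,
            p_merge_conj = p_merge_conj, vocab_fraction = vocab_fraction)
  stopifnot(all(unlist(p) >= 0), all(unlist(p) <= 1))
  structure(p, class = "guideline_profile")
}

#' Default paired guideline profiles
#'
#' The two divergent guidelines used as the package's default study
#' conditions. The "local" guideline annotates bare concept phrases, also
#' marks concept mentions not pertaining to the patient (organisation
#' names), and never merges prepositional or conjunction patterns. The
#' "foreign" guideline extends about 11% of annotations over a preceding
#' article and 3% over a possessive pronoun, skips non-patient mentions,
#' and usually merges a concept with a following body-part prepositional
#' phrase. Both draw 65% of the master vocabulary, so the corpora overlap
#' in — but do not share — their concept inventories.
#'
#' @return A [guideline_profile()].
#' @export
profile_local <- function() {
  guideline_profile(p_article = 0, p_possessive = 0, p_unrelated = 1,
                    p_merge_prep = 0, p_merge_conj = 0, vocab_fraction = 0.65)
}

#' @rdname profile_local
#' @export
profile_foreign <- function() {
  guideline_profile(p_article = 0.11, p_possessive = 0.03, p_unrelated = 0,
                    p_merge_prep = 0.9, p_merge_conj = 0.3,
                    vocab_fraction = 0.65)
}

#' Synthetic corpus configuration
#'
#' Language-side settings shared by any guideline profile applied to the
#' same text stream: corpus dimensions, the target token-level concept
#' density, and the rates at which articles/possessives precede concept
#' mentions in the text (inclusion of those words in the annotation is the
#' guideline's decision, see [guideline_profile()]).
#'
#' @param n_docs,lines_per_doc Corpus dimensions.
#' @param tokens_per_line Mean filler-sentence length in tokens.
#' @param density Target fraction of tokens inside concept annotations
#'   (default 0.11, typical of medical-problem corpora).
#' @param article_rate,possessive_rate Probability that a concept mention is
#'   preceded in the text by an article / possessive pronoun. The marginal
#'   annotation-extension probabilities of a profile cannot exceed these.
#' @param org_rate,prep_rate,conj_rate Fractions of concept-bearing
#'   sentences drawn from organisation-name, prepositional-phrase and
#'   conjunction templates.
#' @param report_types Named weights of report-type labels (metadata
#'   mixture).
#' @param seed RNG seed; identical seeds give byte-identical corpora.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_docs = 100L, lines_per_doc = 8L,
                         tokens_per_line = 9, density = 0.11,
                         article_rate = 0.35, possessive_rate = 0.15,
                         org_rate = 0.08, prep_rate = 0.12, conj_rate = 0.10,
                         report_types = c(note = 1), seed = 1L) {
  stopifnot(n_docs >= 1, lines_per_doc >= 1, tokens_per_line >= 4,
            density > 0, density < 1, article_rate >= 0, article_rate <= 1,
            possessive_rate >= 0, article_rate + possessive_rate <= 1,
            org_rate >= 0, prep_rate >= 0, conj_rate >= 0,
            org_rate + prep_rate + conj_rate <= 1,
            length(report_types) >= 1, all(report_types >= 0),
            sum(report_types) > 0, !is.null(names(report_types)))
  structure(list(n_docs = as.integer(n_docs),
                 lines_per_doc = as.integer(lines_per_doc),
                 tokens_per_line = tokens_per_line, density = density,
                 article_rate = article_rate,
                 possessive_rate = possessive_rate, org_rate = org_rate,
                 prep_rate = prep_rate, conj_rate = conj_rate,
                 report_types = report_types / sum(report_types),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic annotated corpus
#'
#' Builds documents from sentence templates: filler sentences alternate with
#' concept-bearing sentences so that the realised token-level annotation
#' density tracks the configured target (a deterministic controller keeps it
#' within ±0.03 at corpus scale). Concept slots are filled from the
#' profile's vocabulary subset; whether a preceding article or possessive is
#' part of the gold span, whether organisation-context mentions are
#' annotated, and whether prepositional/conjunction patterns are merged are
#' decided by the [guideline_profile()]. Every random decision is drawn
#' unconditionally from the seeded stream, so two runs with the same
#' `config` but different profiles describe the same underlying text with
#' different guidelines — the basis of the curation-recovery tests.
#'
#' @param lexicon A [default_concept_lexicon()]-shaped lexicon.
#' @param profile A [guideline_profile()].
#' @param config A [synth_config()].
#' @param source_label Corpus label.
#' @return A [corpus()].
#' @export
generate_corpus <- function(lexicon = default_concept_lexicon(),
                            profile = guideline_profile(),
                            config = synth_config(),
                            source_label = "synthetic") {
  stopifnot(inherits(profile, "guideline_profile"),
            inherits(config, "synth_config"))
  if (profile$p_article > config$article_rate)
    stop2("p_article (", profile$p_article, ") exceeds the text's article_rate (",
          config$article_rate, "): extension probability unreachable")
  if (profile$p_possessive > config$possessive_rate)
    stop2("p_possessive exceeds possessive_rate: extension probability unreachable")
  articles <- curation_config()$articles
  possessives <- curation_config()$possessives
  p_inc_art <- if (config$article_rate > 0)
    profile$p_article / config$article_rate else 0
  p_inc_pos <- if (config$possessive_rate > 0)
    profile$p_possessive / config$possessive_rate else 0
  kinds <- vapply(lexicon$templates, `[[`, character(1), "kind")

  with_local_seed(config$seed, {
    n_vocab <- max(1L, round(profile$vocab_fraction * length(lexicon$concepts)))
    vocab <- sample(lexicon$concepts, n_vocab)
    base_tok <- 0; base_con <- 0    # profile-invariant density controller

    docs <- vector("list", config$n_docs)
    for (d in seq_len(config$n_docs)) {
      rtype <- sample(names(config$report_types), 1L,
                      prob = config$report_types)
      lines <- vector("list", config$lines_per_doc)
      spans <- list()
      for (li in seq_len(config$lines_per_doc)) {
        concept_line <- base_tok == 0 || base_con / base_tok < config$density
        if (concept_line) {
          u <- runif(1)
          kind <- if (u < config$org_rate) "org"
          else if (u < config$org_rate + config$prep_rate) "prep"
          else if (u < config$org_rate + config$prep_rate + config$conj_rate)
            "conj"
          else "plain"
          idx <- which(kinds == kind)
          tmpl <- lexicon$templates[[idx[sample.int(length(idx), 1L)]]]
          built <- build_concept_line(tmpl, kind, vocab, lexicon, profile,
                                      config, articles, possessives,
                                      p_inc_art, p_inc_pos)
          lines[[li]] <- built$tokens
          if (nrow(built$spans)) {
            built$spans$line <- li
            spans[[length(spans) + 1L]] <- built$spans
          }
          base_con <- base_con + built$core_tokens
        } else {
          len <- max(4L, stats::rpois(1, config$tokens_per_line - 1))
          lines[[li]] <- c(sample(lexicon$filler, len, replace = TRUE), ".")
        }
        base_tok <- base_tok + length(lines[[li]])
      }
      con <- if (length(spans)) do.call(rbind, spans) else empty_concepts()
      docs[[d]] <- annotated_doc(sprintf("%s_%04d", source_label, d), lines,
                                 con, rtype)
    }
    if (abs(base_con / base_tok - config$density) > 0.03)
      stop2("realized concept density ", sprintf("%.3f", base_con / base_tok),
            " is not within 0.03 of target ", config$density,
            ": density unreachable with given templates")
    corpus(source_label, docs)
  })
}

# Fill one template with concepts and guideline decisions. Returns tokens,
# spans (line column unset) and the profile-invariant core token count.
build_concept_line <- function(tmpl, kind, vocab, lexicon, profile, config,
                               articles, possessives, p_inc_art, p_inc_pos) {
  tokens <- character(0)
  spans <- list()
  core <- 0L
  slot_starts <- integer(0); slot_ends <- integer(0)
  body_pos <- NA_integer_
  for (tk in tmpl$tokens) {
    if (tk == "<P>") {
      ptoks <- strsplit(sample(vocab, 1L), " ", fixed = TRUE)[[1]]
      core <- core + length(ptoks)
      include_pre <- FALSE
      if (kind != "org") {
        r <- runif(1)
        w <- runif(1)
        if (r < config$article_rate) {
          pre <- sample(articles, 1L)
          tokens <- c(tokens, pre)
          include_pre <- w < p_inc_art
        } else if (r < config$article_rate + config$possessive_rate) {
          pre <- sample(possessives, 1L)
          tokens <- c(tokens, pre)
          include_pre <- w < p_inc_pos
        }
      }
      s <- length(tokens) + 1L - include_pre
      tokens <- c(tokens, ptoks)
      slot_starts <- c(slot_starts, s)
      slot_ends <- c(slot_ends, length(tokens))
    } else if (tk == "<B>") {
      body_pos <- length(tokens) + 1L
      tokens <- c(tokens, sample(lexicon$body_parts, 1L))
    } else {
      tokens <- c(tokens, tk)
    }
  }
  add_span <- function(s, e) {
    spans[[length(spans) + 1L]] <<-
      data.frame(line = NA_integer_, start = s, end = e, type = "problem",
                 surface = NA_character_, stringsAsFactors = FALSE)
  }
  if (kind == "plain") {
    for (i in seq_along(slot_starts)) add_span(slot_starts[i], slot_ends[i])
  } else if (kind == "prep") {
    merged <- runif(1) < profile$p_merge_prep
    add_span(slot_starts[1], if (merged) body_pos else slot_ends[1])
  } else if (kind == "conj") {
    merged <- runif(1) < profile$p_merge_conj
    if (merged) {
      add_span(slot_starts[1], slot_ends[2])
    } else {
      add_span(slot_starts[1], slot_ends[1])
      add_span(slot_starts[2], slot_ends[2])
    }
  } else if (kind == "org") {
    annotate <- runif(1) < profile$p_unrelated
    if (annotate) add_span(slot_starts[1], slot_ends[1])
  }
  spans <- if (length(spans)) do.call(rbind, spans) else empty_concepts()
  list(tokens = tokens, spans = spans, core_tokens = core)
}

#' Generate a pair of corpora under two guidelines
#'
#' Emulates a local/foreign corpus pair: two corpora built from the same
#' master lexicon and language settings but annotated under different
#' guideline profiles, with overlapping vocabulary subsets (controlled by
#' each profile's `vocab_fraction`), disjoint document ids and independent
#' document streams derived from one shared seed.
#'
#' @param lexicon A shared master lexicon.
#' @param profile_A,profile_B [guideline_profile()]s for the two corpora.
#' @param config_A,config_B [synth_config()]s; their `seed` fields are
#'   overridden by seeds derived from `shared_seed`.
#' @param shared_seed Single seed controlling the pair.
#' @param labels Length-2 character vector of source labels.
#' @return A named list of two [corpus()] objects.
#' @export
generate_paired_corpora <- function(lexicon = default_concept_lexicon(),
                                    profile_A = profile_local(),
                                    profile_B = profile_foreign(),
                                    config_A = synth_config(),
                                    config_B = synth_config(),
                                    shared_seed = 1L,
                                    labels = c("local", "foreign")) {
  stopifnot(length(labels) == 2L, labels[1] != labels[2])
  config_A$seed <- derive_seed(shared_seed, 1L)
  config_B$seed <- derive_seed(shared_seed, 2L)
  out <- list(generate_corpus(lexicon, profile_A, config_A, labels[1]),
              generate_corpus(lexicon, profile_B, config_B, labels[2]))
  names(out) <- labels
  out
}

#' Build a term dictionary from the concept lexicon
#'
#' Turns (a seeded sample of) the master concept phrases into a
#' [build_dictionary()] terminology with one semantic label — the stand-in
#' for a clinical vocabulary with partial coverage of what annotators mark.
#'
#' @param lexicon A [default_concept_lexicon()]-shaped lexicon.
#' @param fraction Fraction of phrases to include (1 = all).
#' @param label Semantic label for all entries.
#' @param seed Seed for the sample when `fraction < 1`.
#' @param base_lexicon Optional base-form lexicon stored with the dictionary.
#' @return A `term_dictionary`.
#' @export
concept_dictionary <- function(lexicon = default_concept_lexicon(),
                               fraction = 1, label = "problem", seed = 1L,
                               base_lexicon = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  phrases <- lexicon$concepts
  if (fraction < 1) {
    n <- max(1L, round(fraction * length(phrases)))
    phrases <- with_local_seed(derive_seed(seed, 97L),
                               sample(phrases, n))
  }
  build_dictionary(data.frame(term = phrases, label = label,
                              stringsAsFactors = FALSE), base_lexicon)
}
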