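---
title: "Pooling annotated clinical corpora for concept extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling annotated clinical corpora for concept extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Annotating clinical text is expensive, so a natural question for any group
building a machine-learning concept tagger is whether an annotated corpus
from *another* institution can substitute for, or supplement, local
annotation effort. The catch is that corpora are annotated under different
guidelines: one site marks "the cough", another marks "cough"; one merges
"pain in the chest" into a single concept, another marks only "pain"; one
marks the disease name inside "cancer clinic", another does not. clinpool
implements a complete test bed for this question: a dictionary + CRF
tagging pipeline, span-level evaluation, automated guideline
reconciliation, pooled cross-validation designs, and a synthetic corpus
generator that makes the whole framework testable without access-restricted
clinical data.

## The tagging pipeline

The unit of text is a tokenized sentence line; concept annotations are
within-line token spans with a semantic type (here `"problem"`:
signs/symptoms and disorders). Three stages mirror the classic
dictionary-plus-learning architecture:

**Lexical normalization and dictionary lookup.** Both the text and a plain
`term → label` dictionary are normalized token-wise: lowercase, strip
punctuation characters, map Greek letters to a marker, map digits to `9`,
then replace by a base form from a `surface → lemma` lexicon. `lookup_all()`
then reports *every* dictionary phrase occurrence, including nested and
overlapping ones, by scanning all token windows up to the longest entry.
Windows range over tokens whose normalized form is non-empty, so
punctuation tokens are transparent ("nausea , vomiting" still matches
"nausea vomiting").

Two normalization details are deliberate choices. First, the pipeline is
*idempotent*: every output is a fixed point, which is what makes cached or
re-normalized dictionaries safe. This forces the Greek marker to be the
lowercase `g` — an uppercase marker could not survive re-application of the
lowercasing step. The marker is therefore ambiguous with a genuine letter
g; the conflation is accepted and harmless for matching. Second, base forms
in a lexicon must themselves be normalization fixed points;
`read_base_lexicon()` enforces this.

**Features.** `extract_features()` emits, for each token, the word and its
lowercase form, prefixes and suffixes of length 1–4, word shape
(`Hb12 → Aa99`) and run-compressed shape, a digit flag, a POS tag, and the
dictionary-match state — `B-`/`I-` of the *longest* dictionary match
covering the token, leftmost on ties — and repeats the same families for
the neighbours at offsets −2..+2, i.e. a five-token window, with
begin/end-of-line sentinels. POS tags come from a pluggable provider; the
built-in `simple_pos_tagger()` is a deterministic closed-class +
suffix-rule tagger, and any function from tokens to tags (e.g. a wrapper
around a biomedical tagger) can be substituted.

**Sequence model.** Spans are BIO-encoded per line. `crf_tagger()` fits a
linear-chain conditional random field over the three labels by L2-penalised
maximum likelihood: the forward–backward gradients and Viterbi decoder are
implemented in C++, and optimisation uses L-BFGS. Training has no
stochastic step, so a fit is fully reproducible from corpus +
configuration. Decoding is tolerant: an illegal leading `I` opens a new
span (the strict CoNLL parser, by contrast, treats it as a file error).
Default regularisation is `lambda = 1`, weak at the corpus sizes used here;
the experiment defaults cap L-BFGS at 60 iterations, which is past
convergence on these corpora while keeping a 375-fit learning curve
affordable.

## Evaluation

`pair_spans()` computes a maximum one-to-one pairing between predicted and
gold spans — exact mode requires both boundaries to agree, overlap mode any
shared token. One-to-one means a single long prediction cannot "match" two
gold spans; the pairing is computed by augmenting-path bipartite matching,
so the reported true-positive count is provably maximal (the test suite
checks it against an exhaustive oracle). Precision, recall and F1 follow
the standard formulas with the zero-denominator convention P = R = F1 = 0.
Corpus-level scores are micro-averaged: counts are pooled over documents
before ratios are formed, matching shared-task convention. Overlap-mode
scores can never fall below exact-mode scores; the experiment engine
asserts this on every run as an internal sanity check.

`phrase_overlap()` quantifies guideline compatibility directly on
annotation surfaces: how many of one corpus's annotation phrases occur in
the other's, exactly, ignoring one start word, or ignoring any single word
(deletions only for phrases of ≥ 2 tokens, case-insensitive on raw
tokens — these are annotation surfaces, not normalized dictionary forms).

## Guideline reconciliation

`curate_corpus()` implements the one reconciliation that is safely
automatable: stripping leading articles (`a, the, any, some, an, this`) and
possessive pronouns (`his, her`) from annotations. Stripping iterates while
the first token is a stop word and at least two tokens remain — this makes
the operation idempotent and guarantees no annotation is emptied or
lengthened. Interior stop words are never touched; differences due to
prepositional phrases, conjunctions, non-patient mentions and concept scope
are left uncorrected deliberately, so their residual cost remains
measurable after curation.

## The synthetic generator as study conditions

`generate_paired_corpora()` emulates the two-institution setting. Documents
are built from sentence templates with concept slots filled from a master
vocabulary of 158 problem phrases (1–4 tokens). The key design idea is the
separation of *language* from *guideline*:

* `synth_config()` holds the language side: corpus dimensions, a target
  token-level concept density of 0.11 (the typical fraction of tokens
  inside medical-problem annotations), and the rates at which articles
  (0.35) and possessives (0.15) precede concept mentions *in the text*.
* `guideline_profile()` holds the annotation side: the marginal
  probability that an annotation is extended over a preceding article
  (`p_article`) or possessive (`p_possessive`), whether organisation-name
  mentions are annotated (`p_unrelated`), whether concept + body-part
  prepositional phrases (`p_merge_prep`) and conjunction lists
  (`p_merge_conj`) are merged into one span, and the fraction of the
  master vocabulary the corpus draws from (`vocab_fraction`).

Every random decision — template, phrase, article presence, extension,
merge — is drawn unconditionally from the seeded stream, so two runs with
the same config but different profiles annotate the *same underlying
text* under different guidelines. This is what makes the curation test
exact: curating a corpus generated with
`p_article = 0.11, p_possessive = 0.03` reproduces the annotation
multiset of the seed-matched zero-probability corpus identically, and the
reported modified fraction estimates `p_article + p_possessive`.

A deterministic controller alternates filler and concept-bearing sentences
so the realised density stays within ±0.03 of target at corpus scale; the
controller state is profile-invariant (it counts core phrase tokens only),
preserving seed-matching. Density targets that templates cannot reach, or
extension probabilities exceeding the text-side rates, are errors.

The default paired profiles mirror a realistic divergence: the *local*
guideline annotates bare phrases, marks non-patient mentions and never
merges; the *foreign* guideline extends 11% of annotations over articles
and 3% over possessives, skips non-patient mentions, merges 90% of
prepositional patterns and 30% of conjunction lists; both draw 65% of the
master vocabulary. The article/possessive numbers are the well-documented
magnitudes for such corpora; the merge rates are order-of-magnitude
choices (the prevalence of those patterns is not quantified anywhere) and
are labelled as such.

What the generator does *not* emulate: real clinical language (sections,
abbreviations, misspellings, de-identification artifacts), multi-line
concepts, assertion status, and annotator noise. Passing experiments
therefore demonstrate that the *framework* reproduces the pooling
phenomena under controlled guideline divergence — not that any specific
clinical corpus pair would show the same numbers.

## Experiment designs and default problem sizes

`make_folds()` builds seeded, balanced k-fold plans (shuffle + round-robin).
`run_cv()` trains on the local training fraction — optionally truncated to
a subset size — plus the entire foreign corpus (never sampled, and never in
a test fold; a leakage guard errors otherwise) and evaluates each test fold
in both modes. `run_cross_corpus()` is the whole-corpus transfer design.
`run_learning_curve()` runs 5×5-fold cross-validation per subset size with
three arms sharing the same local subsets: local-only, pooled, and
pooled-with-curated-foreign. Full-corpus cross-validation defaults to 3
repeats, subset curves to 5, the extra repeats compensating for the higher
variance of small subsets.

The package's default study conditions, used by the acceptance script and
the heavyweight tests, are: local corpus 60 documents, foreign corpus 240
documents (4× local, matching the situation where a large foreign resource
supplements a small local one), 8 lines per document, dictionary covering
60% of the master vocabulary (a terminology never covers everything
annotators mark — and a partial dictionary is what gives the learned
tagger room to beat the dictionary-only baseline), and a geometric subset
grid of 3, 6, 12, 24, 48 local training documents. The grid's lower end
sits where a pilot run showed the local-only tagger still visibly
deficient, because the pooling benefit is a small-corpus phenomenon; its
upper end is the largest size a 5-fold training fraction of 60 documents
permits. With these sizes the learning curve fits 375 CRF models in
roughly ten minutes on one core.

Two analysis conventions are fixed up front. The learning-curve *crossing*
(pooling helps below a critical local size, hurts above it) and the
curated-vs-uncurated comparison are read on exact-span F1, where guideline
incompatibility bites hardest. The pooling *recall* gain is read on
overlap-span recall: pooling should help the tagger *find* concepts, and
overlap matching is the measure of finding a concept irrespective of
boundary convention.

## A worked run

```{r}
library(clinpool)

pair <- generate_paired_corpora(
  config_A = synth_config(n_docs = 60, seed = 1),
  config_B = synth_config(n_docs = 240, seed = 1), shared_seed = 1)
dict <- concept_dictionary(fraction = 0.6, seed = 1)

fit <- crf_tagger(pair$local, dict)
predict(fit, pair$local$documents[[1]])

cv <- run_cv(pooling_spec(pair$local), config = tagger_config(maxit = 60),
             dictionary = dict, repeats = 3, seed = 1)
cv

curve <- run_learning_curve(pair$local, pair$foreign,
                            subset_sizes = c(3, 6, 12, 24, 48), repeats = 5,
                            config = tagger_config(maxit = 60),
                            dictionary = dict, seed = 1)
find_pooling_crossing(curve)
plot(curve)
```

## Known limitations

* Concepts are confined to single lines; multi-line annotation records are
  rejected at parse time with a diagnostic.
* The built-in POS tagger is a heuristic stand-in; its tags are
  self-consistent but not linguistically accurate, and experiments measure
  the pipeline with this provider unless another is plugged in.
* The one-to-one overlap pairing is one of several defensible conventions
  for overlap evaluation; raw counts are exposed so alternatives can be
  recomputed.
* Statistical significance testing across experiment arms is out of scope;
  results report means and standard deviations over repeat × fold cells.
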