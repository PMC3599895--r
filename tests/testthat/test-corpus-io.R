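test_that("annotated_doc validates spans and derives surfaces", {
  d <- example_doc()
  expect_identical(d$concepts$surface, c("abdominal pain", "chest pain"))
  expect_error(annotated_doc("x", list(c("a", "b")), spans(1, 1, 3)),
               "out of bounds")
  expect_error(annotated_doc("x", list(c("a", "b")),
                             rbind(spans(1, 1, 2), spans(1, 1, 2))),
               "duplicate")
  expect_error(annotated_doc("x", list(c("a", "b c"))), "whitespace")
})

test_that("corpus enforces unique doc ids and computes density", {
  d1 <- example_doc()
  d2 <- annotated_doc("ex2", list(c("fever", "noted")), spans(1, 1, 1))
  expect_error(corpus("c", list(d1, d1)), "duplicate doc_ids")
  cp <- corpus("c", list(d1, d2))
  # 4 annotated tokens of 17 total
  expect_equal(concept_density(cp), 5 / 17)
})

test_that("standoff records follow the 1-based line / 0-based token dialect", {
  d <- example_doc()
  tf <- withr::local_tempfile(); af <- withr::local_tempfile()
  recs <- write_standoff(d, tf, af)
  expect_identical(recs[1], 'c="abdominal pain" 1:4 1:5||t="problem"')
  back <- read_standoff(tf, af, doc_id = "ex1")
  expect_equal(back$lines, d$lines)
  expect_equal(back$concepts, sort_concepts_for_test(d$concepts))
})

test_that("standoff round-trip is the identity on generated corpora", {
  corp <- tiny_corpus(n_docs = 5, seed = 9)
  dir <- withr::local_tempdir()
  write_corpus_dir(corp, dir)
  back <- read_corpus_dir(dir, corp$source_label)
  expect_identical(names(back$documents), names(corp$documents))
  for (id in names(corp$documents)) {
    expect_equal(back$documents[[id]]$lines, corp$documents[[id]]$lines)
    expect_equal(back$documents[[id]]$concepts,
                 sort_concepts_for_test(corp$documents[[id]]$concepts))
  }
})

test_that("bad standoff records are rejected with diagnostics, good ones kept", {
  tf <- withr::local_tempfile(lines = "The patient denies any abdominal pain")
  af <- withr::local_tempfile(lines = c(
    'c="abdominal pain" 1:4 1:5||t="problem"',
    'c="pain" 1:5 1:99||t="problem"',          # out of bounds
    'c="pain" 1:3 2:5||t="problem"',           # crosses lines
    "not a record at all"))
  expect_warning(expect_warning(expect_warning(
    d <- read_standoff(tf, af, doc_id = "d"),
    "out-of-bounds"), "spans lines"), "malformed")
  expect_equal(nrow(d$concepts), 1L)
  expect_identical(d$concepts$surface, "abdominal pain")
})

test_that("surface mismatch warns but keeps the token-derived surface", {
  tf <- withr::local_tempfile(lines = "fever noted")
  af <- withr::local_tempfile(lines = 'c="chills" 1:0 1:0||t="problem"')
  expect_warning(d <- read_standoff(tf, af, doc_id = "d"), "differs")
  expect_identical(d$concepts$surface, "fever")
})

test_that("empty annotation file gives a concept-free document", {
  tf <- withr::local_tempfile(lines = "fever noted")
  af <- withr::local_tempfile(lines = character(0))
  d <- read_standoff(tf, af)
  expect_equal(nrow(d$concepts), 0L)
})

test_that("CoNLL encoding matches the BIO convention and round-trips", {
  d <- example_doc()
  lines <- to_conll(d)
  expect_identical(lines[1:6],
                   paste(c("The", "patient", "denies", "any", "abdominal",
                           "pain"), c("O", "O", "O", "O", "B", "I"),
                         sep = "\t"))
  expect_identical(lines[7], "")
  back <- from_conll(lines, doc_id = "ex1")
  expect_equal(back$lines, d$lines)
  expect_equal(back$concepts, sort_concepts_for_test(d$concepts))
  # round-trip on generated documents
  for (doc in tiny_corpus(n_docs = 3, seed = 3)$documents) {
    rt <- from_conll(to_conll(doc), doc_id = doc$doc_id)
    expect_equal(rt$lines, doc$lines)
    expect_equal(rt$concepts, sort_concepts_for_test(doc$concepts))
  }
})

test_that("CoNLL parsing rejects a leading I label with its line number", {
  expect_error(from_conll(c("fever\tI")), "line 1")
  expect_error(from_conll(c("no\tO", "fever\tI")), "line 2")
  expect_error(from_conll("fever\tX"), "malformed")
})

test_that("to_conll refuses overlapping concepts", {
  d <- annotated_doc("x", list(c("a", "b", "c")),
                     rbind(spans(1, 1, 2), spans(1, 2, 3)))
  expect_error(to_conll(d), "overlapping")
})
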