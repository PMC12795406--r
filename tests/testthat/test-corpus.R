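test_that("utterance invariants are enforced with id and field in errors", {
  expect_error(
    utterance("bad1", "toy", c("a", "b"), c(0, 1), "motion",
              list(arg_span(0, 2, "A"))),
    "bad1.*arguments.*overlaps verb span")
  expect_error(
    utterance("bad2", "toy", c("a", "b", "c"), c(1, 2), "motion",
              list(arg_span(0, 1, "A"), arg_span(0, 1, "A"))),
    "bad2.*duplicated role")
  expect_error(
    utterance("bad3", "toy", c("a", "b"), c(0, 1), "no_such_class"),
    "bad3.*verb_class")
  expect_error(
    utterance("bad4", "toy", c("a", "b"), c(0, 1), "motion",
              list(arg_span(1, 3, "P"))),
    "bad4.*span")
  expect_error(corpus(list(utt_avp("x"), utt_avp("x"))), "duplicate")
})

test_that("word_order_pattern orders overt elements by span start", {
  expect_equal(word_order_pattern(utt_avp()), "AVP")
  expect_equal(word_order_pattern(utt_pv()), "PV")
  # multi-word verb: single V letter at verb-span start
  u <- utterance("mw", "toy", c("the", "fox", "is", "hunted"), c(2, 4),
                 "pursuit", list(arg_span(0, 2, "P")))
  expect_equal(word_order_pattern(u), "PV")
  for (p in all_overt_patterns())
    expect_equal(word_order_pattern(utt_from_pattern(p)), p)
})

test_that("word_order_entropy matches closed forms", {
  expect_equal(word_order_entropy(corpus(list(utt_avp("a"), utt_avp("b")))),
               0)
  expect_equal(word_order_entropy(corpus(list(utt_avp("a"), utt_pv("b")))),
               1)
  # frozen closed-form oracle for counts {AVP:40, PV:30, VAP:20, VPA:10}
  utts <- c(lapply(1:40, function(i) utt_from_pattern("AVP", paste0("a", i))),
            lapply(1:30, function(i) utt_from_pattern("PV", paste0("b", i))),
            lapply(1:20, function(i) utt_from_pattern("VAP", paste0("c", i))),
            lapply(1:10, function(i) utt_from_pattern("VPA", paste0("d", i))))
  expect_equal(word_order_entropy(corpus(utts)), 1.8464393, tolerance = 1e-6)
  expect_error(word_order_entropy(corpus(list())), "empty")
})

test_that("entropy bounds hold on generated corpora", {
  for (s in 1:3) {
    corp <- generate_cdu_corpus(preset_language_spec("verb_final_case"),
                                200, s)
    st <- corpus_statistics(corp)
    expect_gte(st$entropy_bits, 0)
    expect_lte(st$entropy_bits, log2(length(st$pattern_counts)) + 1e-12)
    expect_equal(sum(st$pattern_counts), length(corp))
    # pattern string length = overt elements
    for (u in corp$utterances[1:20])
      expect_equal(nchar(word_order_pattern(u)), 1L + length(u$arguments))
  }
})

test_that("corpus_statistics counts roles and pronoun rates", {
  utts <- c(lapply(1:43, function(i) utt_from_pattern("AV", paste0("a", i))),
            lapply(1:57, function(i) utt_from_pattern("PV", paste0("p", i))))
  st <- corpus_statistics(corpus(utts))
  expect_equal(unname(st$role_proportions), c(0.43, 0.57))
  u1 <- utterance("p1", "toy", c("me", "go"), c(1, 2), "motion",
                  list(arg_span(0, 1, "A", "PRON_1SG")))
  st2 <- corpus_statistics(corpus(list(u1)))
  expect_equal(unname(st2$pronoun12_rate_by_role["A"]), 1.0)
})

test_that("JSONL round-trip is byte-identical and lossless", {
  corp <- generate_cdu_corpus(preset_language_spec("verb_initial_voice"),
                              60, 3)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_corpus(corp, f1)
  back <- read_corpus(f1)
  expect_equal(lapply(back$utterances, unclass),
               lapply(corp$utterances, unclass))
  write_corpus(back, f2)
  expect_identical(readBin(f1, "raw", 1e7), readBin(f2, "raw", 1e7))
})

test_that("unicode tokens survive the round-trip", {
  u <- utterance("uni", "toy", c("köpek", "ısırır",
                                 "çocuk-u"), c(1, 2), "contact",
                 list(arg_span(0, 1, "A"), arg_span(2, 3, "P")))
  f <- withr::local_tempfile()
  write_corpus(corpus(list(u)), f)
  expect_equal(read_corpus(f)$utterances[[1]]$tokens, u$tokens)
})

test_that("empty corpus writes a valid header-only file", {
  f <- withr::local_tempfile()
  write_corpus(corpus(list()), f)
  expect_length(readLines(f), 1L)
  expect_length(read_corpus(f)$utterances, 0L)
})

test_that("malformed records are rejected with the utterance id", {
  f <- withr::local_tempfile()
  lines <- c('{"rolepred_corpus":[1],"metadata":{}}',
             paste0('{"id":"bad_overlap","language":"t","tokens":["a","b"],',
                    '"verb":[0,1],"verb_class":"motion",',
                    '"arguments":[{"span":[0,2],"role":"A",',
                    '"nominality":"OTHER"}]}'))
  writeLines(lines, f)
  expect_error(read_corpus(f), "bad_overlap")
  writeLines(c('{"rolepred_corpus":[1],"metadata":{}}',
               '{"id":"m1","language":"t","tokens":["a"]}'), f)
  expect_error(read_corpus(f), "m1.*missing field")
  expect_error(read_corpus(file.path(tempdir(), "no_such_file_xyz.jsonl")),
               "not found")
})

test_that("TSV round-trip preserves annotation", {
  corp <- generate_cdu_corpus(preset_language_spec("verb_final_case"), 30, 9)
  f <- withr::local_tempfile()
  write_corpus(corp, f, format = "tsv")
  back <- read_corpus(f, format = "tsv")
  expect_equal(length(back), length(corp))
  for (i in seq_along(corp$utterances)) {
    expect_equal(back$utterances[[i]]$tokens, corp$utterances[[i]]$tokens)
    expect_equal(word_order_pattern(back$utterances[[i]]),
                 word_order_pattern(corp$utterances[[i]]))
  }
})

test_that("verb class inventory has 48 editable labels", {
  inv <- verb_class_inventory()
  expect_length(inv, 48L)
  expect_false(anyDuplicated(inv) > 0)
})
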