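test_that("lexicon generation is deterministic and Zipfian", {
  sp <- preset_language_spec("verb_medial_rigid")
  l1 <- generate_lexicon(sp, 42)
  l2 <- generate_lexicon(sp, 42)
  expect_identical(l1, l2)
  l3 <- generate_lexicon(sp, 43)
  expect_false(identical(l1$noun, l3$noun))
  all_words <- c(l1$noun, l1$verb, l1$pronoun, l1$`function`)
  expect_false(anyDuplicated(all_words) > 0)

  # zipf_exponent = 0 -> uniform weights
  expect_equal(rolepred:::zipf_weights(10, 0), rep(0.1, 10))

  # empirical frequency of a 100k sample decreases with rank
  set.seed(1)
  draws <- rolepred:::sample_zipf(50, 1, 100000)
  counts <- tabulate(draws, 50)
  expect_lt(cor(seq_len(50), counts, method = "spearman"), -0.9)

  # markers come from the function alphabet and are unique
  expect_true(all(l1$markers %in% l1$`function`))
  expect_false(anyDuplicated(l1$markers) > 0)
})

test_that("cdu generation is a pure function of (spec, n, seed)", {
  sp <- preset_language_spec("verb_final_case")
  c1 <- generate_cdu_corpus(sp, 50, 7)
  c2 <- generate_cdu_corpus(sp, 50, 7)
  expect_identical(lapply(c1$utterances, unclass),
                   lapply(c2$utterances, unclass))
  expect_identical(attr(c1, "generation_log"), attr(c2, "generation_log"))
})

test_that("degenerate spec yields all-AVP corpora", {
  sp <- language_spec("deg", order_distribution = c(AVP = 1),
                      omission_prob = c(A = 0, P = 0), marking = "none")
  corp <- generate_cdu_corpus(sp, 40, 2)
  pats <- vapply(corp$utterances, word_order_pattern, "")
  expect_true(all(pats == "AVP"))
})

test_that("omission statistics match the binomial oracle", {
  sp <- language_spec("om", order_distribution = c(APV = 1),
                      omission_prob = c(A = 0.5, P = 0), marking = "none")
  n <- 2000
  corp <- generate_cdu_corpus(sp, n, 5)
  pv <- mean(vapply(corp$utterances, word_order_pattern, "") == "PV")
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(pv - 0.5), 3 * se)
})

test_that("generation log is the exact oracle for pattern counts", {
  for (nm in c("verb_initial_voice", "verb_medial_rigid",
               "verb_final_case")) {
    corp <- generate_cdu_corpus(preset_language_spec(nm), 300, 11)
    log <- attr(corp, "generation_log")
    pats <- vapply(corp$utterances, word_order_pattern, "")
    expect_identical(unname(c(table(pats))),
                     unname(c(table(log$overt_pattern))))
    expect_identical(sort(unique(pats)), sort(unique(log$overt_pattern)))
  }
})

test_that("empirical pattern distribution matches the analytic expectation", {
  sp <- preset_language_spec("verb_final_case")
  n <- 5000
  corp <- generate_cdu_corpus(sp, n, 23)
  exp_p <- expected_pattern_distribution(sp)
  pats <- factor(vapply(corp$utterances, word_order_pattern, ""),
                 levels = names(exp_p))
  obs <- as.numeric(table(pats)) / n
  se <- sqrt(exp_p * (1 - exp_p) / n)
  expect_true(all(abs(obs - exp_p) < 3 * se + 1e-9))
})

test_that("the three archetype presets have the documented role skews", {
  stats <- lapply(c("verb_initial_voice", "verb_medial_rigid",
                    "verb_final_case"), function(nm)
    corpus_statistics(generate_cdu_corpus(preset_language_spec(nm), 4000,
                                          31)))
  # overt A proportion: > 0.5 for verb-initial/medial, < 0.5 for verb-final
  expect_gt(stats[[1]]$role_proportions["A"], 0.5)
  expect_gt(stats[[2]]$role_proportions["A"], 0.5)
  expect_lt(stats[[3]]$role_proportions["A"], 0.5)
  # role-skewed pronoun usage whenever the spec encodes the skew
  for (st in stats)
    expect_gt(st$pronoun12_rate_by_role["A"], st$pronoun12_rate_by_role["P"])
  # verb-final archetype: "PV" is the most frequent overt pattern
  pc <- stats[[3]]$pattern_counts
  expect_equal(names(pc)[which.max(pc)], "PV")
})

test_that("adu text obeys the stopping rule and shares the lexicon", {
  sp <- preset_language_spec("verb_medial_rigid")
  adu <- generate_adu_text(sp, 1000, 3)
  total <- sum(lengths(adu))
  expect_gte(total, 1000)
  expect_lt(total - length(adu[[length(adu)]]), 1000)
  expect_identical(generate_adu_text(sp, 1000, 3), adu)

  # vocabulary coverage of the paired CDU preset at larger n
  cdu <- generate_cdu_corpus(sp, 400, 3)
  adu_big <- generate_adu_text(sp, 20000, 3)
  cdu_vocab <- unique(unlist(lapply(cdu$utterances, `[[`, "tokens")))
  adu_vocab <- unique(unlist(adu_big))
  expect_gt(mean(cdu_vocab %in% adu_vocab), 0.9)
})

test_that("language spec validation rejects bad probabilities", {
  expect_error(language_spec("x", order_distribution = c(AVP = 0.7)),
               "probability")
  expect_error(language_spec("x", order_distribution = c(XYZ = 1)),
               "permutations")
  expect_error(language_spec("x", order_distribution = c(AVP = 1),
                             lexicon_sizes = c(noun = 0, verb = 2,
                                               pronoun = 3,
                                               `function` = 3)),
               "lexicon_sizes")
})

test_that("language specs round-trip through YAML", {
  sp <- preset_language_spec("verb_final_case")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_language_spec(sp, f)
  sp2 <- read_language_spec(f)
  expect_equal(sp2$order_distribution[names(sp$order_distribution)],
               sp$order_distribution)
  expect_equal(sp2$omission_prob, sp$omission_prob)
  expect_identical(lapply(generate_cdu_corpus(sp2, 20, 4)$utterances,
                          unclass),
                   lapply(generate_cdu_corpus(sp, 20, 4)$utterances,
                          unclass))
})

test_that("stimuli are factorial, lexically matched and order-invariant", {
  sp <- preset_language_spec("verb_medial_rigid")
  d <- stimulus_design(sp, list(voice = c("active", "passive")), 2)
  stim <- generate_stimuli(d, 5)
  expect_length(stim, 4L)
  conds <- attr(stim, "conditions")
  expect_equal(unname(c(table(conds$item))), c(2L, 2L))

  # same content words across cells of one item
  toks <- split(lapply(stim$utterances, `[[`, "tokens"), conds$item)
  lex <- attr(stim, "lexicon")
  content <- function(tk) sort(intersect(unlist(tk), c(lex$noun, lex$verb)))
  for (it in toks) expect_equal(content(it[1]), content(it[2]))

  # shuffled factor levels -> equal multiset of realized token strings
  d2 <- stimulus_design(sp, list(voice = c("passive", "active")), 2)
  stim2 <- generate_stimuli(d2, 5)
  s1 <- sort(vapply(stim$utterances, function(u) paste(u$tokens,
                                                       collapse = " "), ""))
  s2 <- sort(vapply(stim2$utterances, function(u) paste(u$tokens,
                                                        collapse = " "), ""))
  expect_identical(s1, s2)
})

test_that("verb-final case stimuli mark the initial noun per cell", {
  sp <- preset_language_spec("verb_final_deterministic")
  d <- stimulus_design(sp, list(initial_role = c("A_initial", "P_initial"),
                                order = c("verb_medial", "verb_final")), 3)
  stim <- generate_stimuli(d, 8)
  expect_length(stim, 12L)
  lex <- attr(stim, "lexicon")
  conds <- attr(stim, "conditions")
  for (i in seq_along(stim$utterances)) {
    u <- stim$utterances[[i]]
    first <- u$arguments[[1]]
    marker <- u$tokens[first$end]  # case suffix token closes the span
    expected <- if (conds$initial_role[i] == "A_initial") lex$markers[["A"]]
      else lex$markers[["P"]]
    expect_equal(marker, unname(expected))
  }
  expect_error(stimulus_design(sp, list(voice = c("av", "pv"))),
               "incompatible")
})
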