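tiny_config <- function(vocab, seed = 3) {
  srp_config(vocab, embedding_dim = 5, encoder_hidden_dim = 6,
             processor_hidden_dim = 7, classifier_hidden_dim = 5,
             seed = seed, max_epochs = 3)
}

test_that("analytic gradients match finite differences", {
  corp <- generate_cdu_corpus(preset_language_spec("verb_final_case"), 6, 7)
  vocab <- build_vocab(list(corp))
  m <- srp_init(tiny_config(vocab))
  set.seed(9)
  m$params <- m$params + rnorm(length(m$params), 0, 0.05)
  pay <- rolepred:::corpus_payloads(corp, vocab)
  for (stage in c(1L, 0L)) {
    r <- rolepred:::cpp_srp_loss_grad(m$params, m$dims, pay, 0.7, stage,
                                      TRUE)
    set.seed(4)
    idx <- sample(length(m$params), 50)
    num <- vapply(idx, function(j) {
      e <- 1e-5
      p1 <- m$params; p1[j] <- p1[j] + e
      p2 <- m$params; p2[j] <- p2[j] - e
      (rolepred:::cpp_srp_loss_grad(p1, m$dims, pay, 0.7, stage,
                                    FALSE)$loss -
       rolepred:::cpp_srp_loss_grad(p2, m$dims, pay, 0.7, stage,
                                    FALSE)$loss) / (2 * e)
    }, 0)
    expect_lt(max(abs(num - r$grad[idx])), 1e-6)
  }
})

test_that("untrained model assigns exactly 0.5 to both roles", {
  corp <- generate_cdu_corpus(preset_language_spec("verb_medial_rigid"),
                              5, 2)
  vocab <- build_vocab(list(corp))
  m0 <- srp_init(tiny_config(vocab))
  for (u in corp$utterances) {
    tr <- incremental_forward(u, m0)
    expect_true(all(tr$probA[!is.na(tr$probA)] == 0.5))
  }
})

test_that("training_loss closed forms and the spreadsheet oracle hold", {
  u <- utt_pv("l1")
  vocab <- build_vocab(list(list(u$tokens)))
  cfg <- tiny_config(vocab)
  cfg$lambda <- 0
  m0 <- srp_init(cfg)
  # uniform binary role prediction, lambda = 0, one argument -> ln 2
  expect_equal(as.numeric(training_loss(list(u), m0, "main")), log(2),
               tolerance = 1e-12)

  # independent R-side recomputation of the joint loss for a 2-utt batch
  corp <- generate_cdu_corpus(preset_language_spec("verb_final_case"), 2, 13)
  vocab <- build_vocab(list(corp))
  cfg <- tiny_config(vocab)
  cfg$lambda <- 0.7
  m <- srp_init(cfg)
  set.seed(21)
  m$params <- m$params + rnorm(length(m$params), 0, 0.05)
  expected <- mean(vapply(corp$utterances, function(u) {
    tr <- incremental_forward(u, m, want_nextword = TRUE)
    e <- rolepred:::utt_to_elements(u, vocab)
    nw <- -mean(log(tr$nextword[cbind(e$nw, seq_len(tr$n_elements))]))
    pA <- tr$probA[, tr$n_elements]
    role <- -sum(log(ifelse(tr$roles == "A", pA, 1 - pA)))
    role + 0.7 * nw
  }, 0))
  expect_equal(as.numeric(training_loss(corp, m, "main")), expected,
               tolerance = 1e-10)
  expect_error(training_loss(list(c("just", "tokens")), m, "main"),
               "annotated")
})

test_that("element encoding is deterministic and order-sensitive", {
  corp <- generate_cdu_corpus(preset_language_spec("verb_medial_rigid"),
                              10, 4)
  vocab <- build_vocab(list(corp))
  m <- srp_init(tiny_config(vocab))
  set.seed(2)
  m$params <- m$params + rnorm(length(m$params), 0, 0.05)
  w <- vocab[3:4]  # two real vocabulary words
  v1 <- embed_element(c(w[1], w[2]), m)
  expect_identical(v1, embed_element(c(w[1], w[2]), m))
  expect_false(isTRUE(all.equal(v1, embed_element(c(w[2], w[1]), m))))
  expect_error(embed_element(character(0), m), "empty span")
})

test_that("hash_random embeddings are stable across models and processes", {
  vocab <- c("<unk>", "<eos>", "blimp", "zorp")
  cfg <- tiny_config(vocab)
  cfg$embedding_mode <- "hash_random"
  m1 <- srp_init(cfg)
  m2 <- srp_init(cfg)
  expect_identical(embed_element("zorp", m1), embed_element("zorp", m2))
  # out-of-vocabulary surfaces map to <unk>, identically every time
  expect_identical(embed_element("never_seen", m1),
                   embed_element("<unk>", m1))
  # the hash itself is a pure function of the surface bytes
  expect_identical(rolepred:::surface_hash("zorp"),
                   rolepred:::surface_hash("zorp"))
})

test_that("trajectory shape follows the element sequence", {
  u <- utt_avp("shape")
  vocab <- build_vocab(list(list(u$tokens)))
  m <- srp_init(tiny_config(vocab))
  tr <- incremental_forward(u, m)
  expect_equal(tr$n_elements, 3L)        # [the fox] [hunts] [the chicken]
  expect_equal(sum(!is.na(tr$probA[1, ])), 3L)
  expect_equal(sum(!is.na(tr$probA[2, ])), 1L)
  # argument entries appear from their time point onward, never disappear
  for (j in 1:2) {
    seen <- !is.na(tr$probA[j, ])
    expect_true(all(diff(seen) >= 0))
  }
})

test_that("pretraining is deterministic and reduces held-out perplexity", {
  sp <- preset_language_spec("verb_medial_rigid")
  adu <- generate_adu_text(sp, 3000, 6)
  vocab <- build_vocab(list(adu))
  cfg <- srp_config(vocab, embedding_dim = 8, encoder_hidden_dim = 8,
                    processor_hidden_dim = 12, classifier_hidden_dim = 8,
                    seed = 5, max_epochs = 3)
  m1 <- pretrain(adu, cfg)
  m2 <- pretrain(adu, cfg)
  expect_identical(m1$params, m2$params)
  log <- m1$log
  ep0 <- log$nw_loss[log$epoch == 0]
  expect_lt(min(log$nw_loss), ep0)
  expect_true("pretrain" %in% m1$provenance$stages)
  # the role classifier output layer is untouched by pretraining
  offs <- rolepred:::srp_offsets(m1$dims)
  expect_true(all(m1$params[rolepred:::block_idx(offs, "W2r")] == 0))
})

test_that("pretraining on a disjoint lexicon is a negative control", {
  spx <- preset_language_spec("verb_medial_rigid")
  spy <- preset_language_spec("verb_final_case")
  adux <- generate_adu_text(spx, 4000, 6)
  aduy <- generate_adu_text(spy, 1500, 60)  # different seed -> new lexicon
  vocab <- build_vocab(list(adux, aduy))
  cfg <- srp_config(vocab, embedding_dim = 8, encoder_hidden_dim = 8,
                    processor_hidden_dim = 12, classifier_hidden_dim = 8,
                    seed = 5, max_epochs = 4)
  m <- pretrain(adux, cfg)
  loss_x <- attr(training_loss(adux[1:50], m, "pretrain"), "nw_loss")
  loss_y <- attr(training_loss(aduy[1:50], m, "pretrain"), "nw_loss")
  expect_gt(loss_y, loss_x + 1)
  expect_gt(loss_y, 0.7 * log(length(vocab)))
})

test_that("label-shuffled control stays at the label-proportion baseline", {
  sp <- preset_language_spec("verb_final_deterministic")
  corp <- generate_cdu_corpus(sp, 500, 77)
  # destroy the label signal: roles reassigned by a fair coin
  set.seed(8)
  shuffled <- lapply(corp$utterances, function(u) {
    if (length(u$arguments) == 2 && runif(1) < 0.5) {
      r1 <- u$arguments[[1]]$role
      u$arguments[[1]]$role <- u$arguments[[2]]$role
      u$arguments[[2]]$role <- r1
    } else if (length(u$arguments) == 1) {
      u$arguments[[1]]$role <- sample(c("A", "P"), 1)
    }
    u
  })
  sc <- corpus(shuffled)
  vocab <- build_vocab(list(sc))
  cfg <- srp_config(vocab, seed = 5, max_epochs = 4)
  m <- train_main(srp_init(cfg), corpus(shuffled[1:380]),
                  corpus(shuffled[381:440]), from_scratch = TRUE)
  test_utts <- shuffled[441:500]
  correct <- unlist(lapply(test_utts, function(u) {
    tr <- incremental_forward(u, m)
    (tr$probA[, tr$n_elements] >= 0.5) == (tr$roles == "A")
  }))
  se <- sqrt(0.25 / length(correct))
  expect_lt(abs(mean(correct) - 0.5), 3 * se)
})

test_that("main training learns the deterministic cue", {
  fx <- cached_det_model()
  acc <- mean(unlist(lapply(fx$test$utterances, function(u) {
    tr <- incremental_forward(u, fx$model)
    (tr$probA[, tr$n_elements] >= 0.5) == (tr$roles == "A")
  })))
  expect_gte(acc, 0.95)
  # both loss components are logged separately
  expect_true(all(c("nw_loss", "role_loss") %in% colnames(fx$model$log)))
  expect_error(train_main(srp_init(fx$model$config), fx$train, fx$val),
               "not pretrained")
})

test_that("monotone information contract holds on the cue preset", {
  fx <- cached_det_model()
  # paired: the same argument before vs after the verb has been seen
  diffs <- unlist(lapply(fx$test$utterances, function(u) {
    tr <- incremental_forward(u, fx$model)
    recs <- extract_records(tr, u)
    out <- c()
    for (r in unique(recs$role)) {
      rr <- recs[recs$role == r, ]
      if (any(!rr$after_verb) && any(rr$after_verb))
        out <- c(out, max(rr$p_correct[rr$after_verb]) -
                   rr$p_correct[!rr$after_verb][1])
    }
    out
  }))
  # >= up to numerical saturation at ceiling
  expect_gte(mean(diffs), -1e-3)
})

test_that("save/load reproduces bit-identical trajectories", {
  fx <- cached_det_model()
  f <- withr::local_tempfile(fileext = ".json")
  save_srp_model(fx$model, f)
  m2 <- load_srp_model(f)
  expect_identical(m2$params, fx$model$params)
  for (u in fx$test$utterances[1:5])
    expect_identical(incremental_forward(u, m2)$probA,
                     incremental_forward(u, fx$model)$probA)
})

test_that("k-fold evaluation partitions the corpus exactly", {
  corp <- generate_cdu_corpus(preset_language_spec("verb_final_case"),
                              100, 15)
  vocab <- build_vocab(list(corp))
  cfg <- srp_config(vocab, embedding_dim = 6, encoder_hidden_dim = 6,
                    processor_hidden_dim = 8, classifier_hidden_dim = 6,
                    seed = 9, max_epochs = 1)
  cv <- kfold_evaluate(corp, 10, cfg)
  expect_equal(unname(c(table(cv$folds))), rep(10L, 10))
  expect_true(all(!vapply(cv$trajectories, is.null, TRUE)))
  cv2_folds <- with_seed_folds <- kfold_evaluate(corp, 10, cfg,
                                                 trace = FALSE)$folds
  expect_identical(cv$folds, cv2_folds)
  expect_error(kfold_evaluate(corpus(corp$utterances[1:5]), 10, cfg),
               "smaller than k")
})
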