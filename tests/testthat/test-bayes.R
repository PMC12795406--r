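fast_spec <- function(...) {
  regression_spec(chains = 2L, iter = 400L, warmup = 300L,
                  adapt_delta = 0.9, ...)
}

test_that("squeeze transform has the documented fixed points", {
  expect_equal(squeeze_to_open_interval(0, 100), 0.005)
  expect_equal(squeeze_to_open_interval(1, 100), 0.995)
  expect_equal(squeeze_to_open_interval(0.5, 7), 0.5)
  expect_equal(squeeze_to_open_interval(0.5, 12345), 0.5)
  p <- c(0, 0.2, 1)
  s <- squeeze_to_open_interval(p, 10)
  expect_true(all(s > 0 & s < 1))
  # identity-approaching as n grows
  expect_lt(abs(squeeze_to_open_interval(0.2, 1e6) - 0.2), 1e-6)
})

test_that("build_design produces the combinatorial column count", {
  recs <- expand.grid(after_argument = c(FALSE, TRUE),
                      after_verb = c(FALSE, TRUE),
                      role = c("A", "P"), language = c("L1", "L2"),
                      stringsAsFactors = FALSE)
  recs <- recs[rep(seq_len(nrow(recs)), 3), ]
  recs$p_correct <- 0.5
  recs$sentence_id <- as.character(seq_len(nrow(recs)))
  spec <- regression_spec(fixed_terms = c("after_argument", "after_verb",
                                          "role", "language"),
                          interactions =
                            "after_argument*after_verb*role*language",
                          group_slopes = c("after_argument", "after_verb",
                                           "role"))
  des <- build_design(recs, spec)
  # the full crossing spans exactly the 2x2x2x2 cell basis
  expect_equal(ncol(des$X), prod(c(2L, 2L, 2L, 2L)))
  expect_equal(qr(des$X)$rank, ncol(des$X))
  expect_equal(ncol(des$R), 4L)  # random intercept + 3 slopes

  # dropping a term removes exactly its columns
  spec2 <- regression_spec(fixed_terms = c("after_argument", "after_verb",
                                           "role"),
                           interactions = character(0))
  expect_equal(ncol(build_design(recs, spec2)$X), 4L)

  recs$language <- "L1"
  expect_error(build_design(recs, spec), "'language' has a single level")
  expect_error(build_design(recs[0, ], spec), "empty")
})

test_that("treatment coding respects declared reference levels", {
  recs <- sim_beta_records(100)
  spec <- regression_spec(fixed_terms = "role", interactions = character(0),
                          group_by = NULL, ref_levels = list(role = "P"))
  des <- build_design(recs, spec)
  expect_true("roleA" %in% colnames(des$X))
})

test_that("rhat and ess agree with theory on synthetic chains", {
  set.seed(42)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_lt(rhat(iid), 1.01)
  expect_gt(ess_bulk(iid), 0.6 * 4000)
  expect_lt(ess_bulk(iid), 1.6 * 4000)
  # AR(1) with known autocorrelation: ESS ~ N (1-rho)/(1+rho)
  rho <- 0.8
  ar <- vapply(1:4, function(i)
    as.numeric(stats::arima.sim(list(ar = rho), 2000)), numeric(2000))
  e <- ess_bulk(ar)
  theory <- 8000 * (1 - rho) / (1 + rho)
  expect_gt(e, 0.5 * theory)
  expect_lt(e, 2.0 * theory)
  # diverged chains are detected
  bad <- cbind(rnorm(500), rnorm(500) + 3)
  expect_gt(rhat(bad), 1.2)
})

test_that("intercept-only model recovers a symmetric 0.5 response", {
  recs <- with_seed(3, data.frame(
    p_correct = rbeta(400, 0.5 * 30, 0.5 * 30)))
  spec <- fast_spec(fixed_terms = character(0),
                    interactions = character(0), group_by = NULL, seed = 4)
  fit <- suppressWarnings(
    fit_beta_hierarchical(build_design(recs, spec, squeeze = FALSE)))
  ep <- posterior_epred(fit, data.frame(x = 1))
  expect_lt(abs(mean(ep) - 0.5), 0.02)
})

test_that("fixed-effect recovery and epred on a simple two-group design", {
  recs <- sim_beta_records(800, beta = c(0, 0, 0.45), sd_g = 0.2, G = 40,
                           seed = 11)
  spec <- fast_spec(fixed_terms = "role", interactions = character(0),
                    group_slopes = character(0), seed = 5)
  fit <- suppressWarnings(fit_beta_hierarchical(build_design(recs, spec)))
  sm <- posterior_summary(fit)
  co <- sm[sm$parameter == "roleP", ]
  expect_gt(co$upper, 0.3)
  expect_lt(co$lower, 0.6)
  # intercept cell mean near logistic(0) = 0.5
  ep <- posterior_epred(fit, data.frame(role = "A"))
  expect_lt(abs(mean(ep) - 0.5), 0.05)
  expect_error(posterior_epred(fit, data.frame(role = "X")), "unseen")
})

test_that("language contrasts recover a known 0.10 gap and antisymmetry", {
  with_seed(7, {
    n <- 1200
    lang <- sample(c("L1", "L2"), n, replace = TRUE)
    mu <- ifelse(lang == "L1", 0.60, 0.70)
    y <- rbeta(n, mu * 30, (1 - mu) * 30)
    recs <- data.frame(p_correct = pmin(pmax(y, 1e-6), 1 - 1e-6),
                       language = lang, stringsAsFactors = FALSE)
  })
  spec <- fast_spec(fixed_terms = "language", interactions = character(0),
                    group_by = NULL, seed = 8)
  fit <- suppressWarnings(fit_beta_hierarchical(build_design(recs, spec)))
  cells <- data.frame(language = c("L1", "L2"))
  ct <- pairwise_language_contrasts(fit, cells)
  d21 <- ct[ct$language1 == "L2" & ct$language2 == "L1", ]
  expect_gt(d21$u95, 0.10 - 0.04)
  expect_lt(d21$l95, 0.10 + 0.04)
  d12 <- ct[ct$language1 == "L1" & ct$language2 == "L2", ]
  expect_equal(d12$mean, -d21$mean)
  expect_equal(d12$l95, -d21$u95)
  self <- ct[ct$language1 == "L1" & ct$language2 == "L1", ]
  expect_equal(self$mean, 0)
  expect_equal(self$l95, 0)
  expect_true(self$suppressed)
})

test_that("prior predictive cell means are weakly informative", {
  recs <- sim_beta_records(200)
  des <- build_design(recs, regression_spec(
    fixed_terms = c("after_argument", "role"), interactions = character(0),
    group_by = NULL))
  pp <- prior_predict_cell_means(des, ndraws = 400, seed = 2)
  expect_true(all(pp > 0 & pp < 1))
  expect_lt(min(pp), 0.05)
  expect_gt(max(pp), 0.95)
})

test_that("diagnostics gate flags every reported fit", {
  recs <- sim_beta_records(300, G = 30, seed = 19)
  spec <- fast_spec(fixed_terms = "role", interactions = character(0),
                    group_slopes = character(0), seed = 9)
  fit <- suppressWarnings(fit_beta_hierarchical(build_design(recs, spec)))
  d <- fit$diagnostics
  gate <- !any(!is.na(d$rhat) & (d$rhat >= 1.01 | d$ess_bulk <= 400 |
                                   d$ess_tail <= 400))
  expect_identical(fit$converged, gate)
  expect_true(all(c("rhat", "ess_bulk", "ess_tail") %in% colnames(d)))
  expect_equal(nrow(d), length(fit$par_names))
})

test_that("PSIS-LOO agrees with exact leave-one-out refitting", {
  recs <- sim_beta_records(20, beta = c(0.3, 0.6, -0.4), G = 20, seed = 23)
  spec <- regression_spec(fixed_terms = c("after_argument", "role"),
                          interactions = character(0), group_by = NULL,
                          chains = 2, iter = 600, warmup = 300, seed = 31)
  des <- build_design(recs, spec, squeeze = FALSE)
  fit <- suppressWarnings(fit_beta_hierarchical(des))
  psis <- loo_elpd(fit$log_lik)
  exact <- vapply(seq_len(nrow(recs)), function(i) {
    des_i <- build_design(recs[-i, ], spec, squeeze = FALSE)
    fit_i <- suppressWarnings(fit_beta_hierarchical(des_i))
    B <- rolepred:::beta_draws_matrix(fit_i)
    phi <- exp(as.vector(fit_i$draws[, , fit_i$p + 1]))
    Xi <- stats::model.matrix(des_i$formula, recs[i, , drop = FALSE],
                              xlev = fit_i$xlevels)[, fit_i$x_names,
                                                    drop = FALSE]
    mu <- stats::plogis(as.vector(Xi %*% t(B)))
    ll <- stats::dbeta(recs$p_correct[i], mu * phi, (1 - mu) * phi,
                       log = TRUE)
    rolepred:::logsumexp(ll) - log(length(ll))
  }, 0)
  expect_lt(abs(psis$elpd_loo - sum(exact)), 1.0)
  expect_true(all(psis$pareto_k < 0.7 | is.na(psis$pareto_k)))
})

test_that("stacking weights form a simplex and handle duplicates", {
  set.seed(5)
  lpd <- matrix(rnorm(200), 100, 2)
  w <- stacking_weights(lpd)
  expect_equal(sum(w), 1, tolerance = 1e-8)
  expect_true(all(w >= 0))
  wdup <- stacking_weights(cbind(lpd[, 1], lpd[, 1], lpd[, 2]))
  expect_equal(sum(wdup), 1, tolerance = 1e-8)
  expect_error(stacking_weights(lpd[, 1, drop = FALSE]), NA)
})

test_that("compare_loo_stacking validates the shared response", {
  recs <- sim_beta_records(250, G = 25, seed = 29)
  spec1 <- fast_spec(fixed_terms = c("after_argument", "role"),
                     interactions = character(0),
                     group_slopes = character(0), seed = 12)
  spec2 <- fast_spec(fixed_terms = "role", interactions = character(0),
                     group_slopes = character(0), seed = 12)
  f1 <- suppressWarnings(fit_beta_hierarchical(build_design(recs, spec1)))
  f2 <- suppressWarnings(fit_beta_hierarchical(build_design(recs, spec2)))
  cmp <- compare_loo_stacking(list(full = f1, reduced = f2))
  expect_equal(sum(cmp$weights), 1, tolerance = 1e-8)
  recs2 <- recs; recs2$p_correct <- rev(recs2$p_correct)
  f3 <- suppressWarnings(fit_beta_hierarchical(build_design(recs2, spec2)))
  expect_error(compare_loo_stacking(list(f1, f3)), "identical response")
})

test_that("single-item stimulus regression warns and drops the grouping", {
  recs <- with_seed(4, data.frame(
    p_correct = rbeta(40, 14, 6), role = rep(c("A", "P"), 20),
    voice = rep(c("active", "passive"), each = 20), item = 1L,
    stringsAsFactors = FALSE))
  expect_warning(
    fit <- fit_stimulus_regression(recs, "voice", chains = 2, iter = 600,
                                   warmup = 300, seed = 3),
    "single stimulus item")
  expect_equal(fit$q, 0L)
})
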