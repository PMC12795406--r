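#' Squeeze responses from [0,1] to the open interval (0,1)
#'
#' The beta likelihood is undefined at the boundaries; the standard
#' compression `y' = (y (n-1) + 1/2) / n` maps 0 and 1 strictly inside
#' while approaching the identity as the sample size grows.
#'
#' @param p numeric vector in \[0,1\].
#' @param n sample size used for the compression (>= 1).
#' @return numeric vector strictly inside (0,1).
#' @export
squeeze_to_open_interval <- function(p, n) {
  stopifnot(n >= 1, all(p >= 0), all(p <= 1))
  (p * (n - 1) + 0.5) / n
}

#' Specification of a hierarchical beta regression
#'
#' @param fixed_terms character vector of main-effect column names.
#' @param interactions character vector of interaction terms (R formula
#'   syntax), e.g. `"after_argument:after_verb:role:language"`.
#' @param group_by grouping column for random effects (`NULL` = none).
#' @param group_slopes columns with by-group random slopes (a random
#'   intercept is always included when `group_by` is set).
#' @param phi_prior `"halfnormal"` (Half-Normal(0,10)) or `"exponential"`
#'   (Exponential(1)) prior for the precision parameter.
#' @param ref_levels named list factor -> reference level (default:
#'   alphabetically first).
#' @param chains,iter,warmup sampler settings (post-warmup draws per
#'   chain).
#' @param adapt_delta dual-averaging target acceptance statistic.
#' @param max_treedepth NUTS maximum tree depth.
#' @param seed integer sampler seed.
#' @return a list of class `rp_regression_spec`.
#' @export
regression_spec <- function(fixed_terms = c("after_argument", "after_verb",
                                            "role", "language",
                                            "nominality", "verb_class"),
                            interactions =
                              c("after_argument*after_verb*role*language",
                                "nominality:role"),
                            group_by = "sentence_id",
                            group_slopes = c("after_argument", "after_verb",
                                             "role"),
                            phi_prior = c("halfnormal", "exponential"),
                            ref_levels = NULL,
                            chains = 4L, iter = 1000L, warmup = 500L,
                            adapt_delta = 0.8, max_treedepth = 10L,
                            seed = 1L) {
  phi_prior <- match.arg(phi_prior)
  structure(list(fixed_terms = fixed_terms, interactions = interactions,
                 group_by = group_by, group_slopes = group_slopes,
                 phi_prior = phi_prior, ref_levels = ref_levels,
                 chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), adapt_delta = adapt_delta,
                 max_treedepth = as.integer(max_treedepth),
                 seed = as.integer(seed)),
            class = "rp_regression_spec")
}

#' Build the regression design from a records table
#'
#' Treatment coding with declared (default alphabetical) reference
#' levels; the four-way position x role x language interaction expands to
#' the full cell basis. Character columns become factors; single-level
#' factors are rejected by name.
#'
#' @param records data frame of predictability records (response column
#'   `p_correct`, already squeezed into (0,1) by the caller or here via
#'   `squeeze`).
#' @param spec an [regression_spec()].
#' @param squeeze apply [squeeze_to_open_interval()] with
#'   `n = nrow(records)` to the response (default TRUE).
#' @return a list of class `rp_design` with `y`, `X`, `R`, `group`,
#'   `formula`, `xlevels` and the spec.
#' @export
build_design <- function(records, spec = regression_spec(), squeeze = TRUE) {
  if (!nrow(records)) stop("empty records table", call. = FALSE)
  if (!"p_correct" %in% colnames(records))
    stop("records must contain p_correct", call. = FALSE)
  vars <- unique(unlist(strsplit(c(spec$fixed_terms, spec$interactions),
                                 "[:*]")))
  miss <- setdiff(vars, colnames(records))
  if (length(miss))
    stop("records lack term column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dat <- records
  for (v in vars) {
    if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
    if (is.factor(dat[[v]])) {
      dat[[v]] <- droplevels(dat[[v]])
      if (nlevels(dat[[v]]) < 2)
        stop(sprintf("factor '%s' has a single level", v), call. = FALSE)
      ref <- spec$ref_levels[[v]]
      if (!is.null(ref)) dat[[v]] <- stats::relevel(dat[[v]], ref = ref)
    }
  }
  terms_all <- c(spec$fixed_terms, spec$interactions)
  fml <- if (length(terms_all)) stats::reformulate(terms_all) else
    stats::as.formula("~1")
  X <- stats::model.matrix(fml, dat)
  y <- records$p_correct
  if (squeeze) y <- squeeze_to_open_interval(y, nrow(records))
  if (any(y <= 0) || any(y >= 1))
    stop("response must lie strictly inside (0,1); use squeeze = TRUE",
         call. = FALSE)

  has_group <- !is.null(spec$group_by) && spec$group_by %in% colnames(records)
  if (!is.null(spec$group_by) && !has_group)
    stop("grouping column '", spec$group_by, "' not found", call. = FALSE)
  if (has_group) {
    gf <- factor(records[[spec$group_by]])
    slopes <- intersect(spec$group_slopes, colnames(dat))
    Rm <- stats::model.matrix(
      if (length(slopes)) stats::reformulate(slopes) else ~1, dat)
    group <- as.integer(gf) - 1L
    group_levels <- levels(gf)
  } else {
    Rm <- matrix(0, nrow(records), 0)
    group <- integer(nrow(records))
    group_levels <- character(0)
  }
  xlevels <- lapply(dat[intersect(vars, colnames(dat))],
                    function(col) if (is.factor(col)) levels(col) else NULL)
  xlevels <- xlevels[!vapply(xlevels, is.null, TRUE)]
  structure(list(y = y, X = X, R = Rm, group = group,
                 group_levels = group_levels, formula = fml,
                 xlevels = xlevels, spec = spec, n = nrow(records)),
            class = "rp_design")
}

#' Fit the hierarchical Bayesian beta regression
#'
#' Logit link for the mean, log link for the precision; Normal(0,1)
#' priors on slopes, Student-t(3,0,2.5) on the intercept and the group
#' standard deviations (non-centered parameterization), Half-Normal(0,10)
#' or Exponential(1) on the precision. Sampling uses the package's NUTS
#' implementation. The fit is flagged `converged = FALSE` (with a loud
#' warning and a per-parameter report) if any split-R-hat >= 1.01 or any
#' bulk/tail ESS <= 400; `fail_on_diagnostics = TRUE` upgrades the
#' warning to an error. The pointwise log-likelihood matrix is retained
#' for LOO.
#'
#' @param design an [build_design()] result.
#' @param spec overrides `design$spec` if supplied.
#' @param fail_on_diagnostics error (instead of warn) on diagnostic
#'   failure.
#' @return an object of class `rp_beta_fit`.
#' @export
fit_beta_hierarchical <- function(design, spec = design$spec,
                                  fail_on_diagnostics = FALSE) {
  X <- design$X; Rm <- design$R; y <- design$y
  p <- ncol(X); q <- ncol(Rm)
  G <- max(1L, length(design$group_levels))
  D <- p + q * G + q + 1L
  phi_code <- if (spec$phi_prior == "halfnormal") 0L else 1L
  has_int <- colnames(X)[1] == "(Intercept)"

  par_names <- c(colnames(X),
                 if (q > 0) as.vector(outer(colnames(Rm), design$group_levels,
                                            function(s, g)
                                              sprintf("z[%s,%s]", g, s))),
                 if (q > 0) sprintf("log_sd_%s", colnames(Rm)),
                 "log_phi")
  # z layout is (slope, group) column-major: slope index fastest
  if (q > 0) {
    zn <- character(q * G)
    for (gi in seq_len(G)) for (j in seq_len(q))
      zn[(gi - 1) * q + j] <- sprintf("z[%s,%s]", design$group_levels[gi],
                                      colnames(Rm)[j])
    par_names <- c(colnames(X), zn, sprintf("log_sd_%s", colnames(Rm)),
                   "log_phi")
  }

  arr <- array(NA_real_, c(spec$iter, spec$chains, D))
  divergences <- integer(spec$chains)
  for (ch in seq_len(spec$chains)) {
    init <- with_seed((spec$seed + 7919L * ch) %% 2147483647L, {
      b <- rnorm(p, 0, 0.1)
      if (has_int) b[1] <- stats::qlogis(mean(y)) + rnorm(1, 0, 0.1)
      c(b, rnorm(q * G, 0, 0.1), rnorm(q, log(0.3), 0.1),
        log(10) + rnorm(1, 0, 0.1))
    })
    res <- with_seed((spec$seed + 104729L * ch) %% 2147483647L,
      cpp_beta_nuts(y, X, Rm, design$group, G, phi_code, has_int, init,
                    spec$warmup, spec$iter, spec$adapt_delta,
                    spec$max_treedepth))
    arr[, ch, ] <- res$draws
    divergences[ch] <- res$divergences
  }

  diag_tab <- mcmc_diagnostics(arr, par_names)
  bad <- diag_tab[!is.na(diag_tab$rhat) &
                    (diag_tab$rhat >= 1.01 | diag_tab$ess_bulk <= 400 |
                       diag_tab$ess_tail <= 400), , drop = FALSE]
  converged <- nrow(bad) == 0
  if (!converged) {
    msg <- sprintf(
      "beta regression did not converge: %d parameter(s) fail diagnostics (worst rhat %.3f, min ESS %.0f)",
      nrow(bad), max(bad$rhat, na.rm = TRUE),
      min(c(bad$ess_bulk, bad$ess_tail), na.rm = TRUE))
    if (fail_on_diagnostics) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }

  stacked <- matrix(aperm(arr, c(1, 2, 3)), spec$iter * spec$chains, D)
  log_lik <- cpp_beta_loglik(y, X, Rm, design$group, G, stacked)

  structure(list(draws = arr, par_names = par_names, p = p, q = q, G = G,
                 formula = design$formula, xlevels = design$xlevels,
                 x_names = colnames(X), y = y,
                 diagnostics = diag_tab, converged = converged,
                 divergences = divergences, log_lik = log_lik,
                 spec = spec),
            class = "rp_beta_fit")
}

#' @export
print.rp_beta_fit <- function(x, ...) {
  cat(sprintf(
    "<rp_beta_fit> %d fixed effects, %d group(s) x %d slope(s), %d chains x %d draws\n",
    x$p, x$G, x$q, dim(x$draws)[2], dim(x$draws)[1]))
  cat(sprintf("  converged: %s (max rhat %.3f, min bulk ESS %.0f, divergences %d)\n",
              x$converged, max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess_bulk, na.rm = TRUE),
              sum(x$divergences)))
  invisible(x)
}

#' Posterior summary of the fixed effects
#'
#' @param fit an `rp_beta_fit`.
#' @param prob credible-interval mass (default 0.95).
#' @return data frame with posterior mean, interval bounds and
#'   diagnostics per fixed-effect coefficient (plus sd and phi rows).
#' @export
posterior_summary <- function(fit, prob = 0.95) {
  keep <- c(seq_len(fit$p),
            if (fit$q > 0) seq.int(fit$p + fit$q * fit$G + 1,
                                   fit$p + fit$q * fit$G + fit$q),
            fit$p + fit$q * fit$G + fit$q + 1)
  a <- (1 - prob) / 2
  rows <- lapply(keep, function(j) {
    d <- as.vector(fit$draws[, , j])
    data.frame(parameter = fit$par_names[j], mean = mean(d),
               lower = quantile(d, a, names = FALSE),
               upper = quantile(d, 1 - a, names = FALSE),
               rhat = fit$diagnostics$rhat[j],
               ess_bulk = fit$diagnostics$ess_bulk[j],
               ess_tail = fit$diagnostics$ess_tail[j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

beta_draws_matrix <- function(fit) {
  matrix(fit$draws[, , seq_len(fit$p)], dim(fit$draws)[1] * dim(fit$draws)[2],
         fit$p)
}

#' Population-level posterior expected values
#'
#' Cell means on the probability scale for new covariate combinations
#' (random effects at zero).
#'
#' @param fit an `rp_beta_fit`.
#' @param newdata data frame of covariate combinations; factor columns
#'   must use levels seen in fitting.
#' @return draws matrix, `nrow(newdata)` x total draws.
#' @export
posterior_epred <- function(fit, newdata) {
  for (v in names(fit$xlevels)) {
    if (!v %in% colnames(newdata)) next
    lev <- fit$xlevels[[v]]
    unseen <- setdiff(unique(as.character(newdata[[v]])), lev)
    if (length(unseen))
      stop(sprintf("unseen level(s) of '%s': %s", v,
                   paste(unseen, collapse = ", ")), call. = FALSE)
    newdata[[v]] <- factor(newdata[[v]], levels = lev)
  }
  Xn <- stats::model.matrix(fit$formula, newdata, xlev = fit$xlevels)
  if (!all(colnames(Xn) == fit$x_names))
    Xn <- Xn[, fit$x_names, drop = FALSE]
  stats::plogis(Xn %*% t(beta_draws_matrix(fit)))
}

#' Cell means with 66% and 95% credible intervals
#'
#' @param fit an `rp_beta_fit`.
#' @param newdata covariate grid (one row per cell).
#' @return `newdata` augmented with posterior `mean`, `l66/u66`,
#'   `l95/u95` columns on the probability scale.
#' @export
cell_means <- function(fit, newdata) {
  ep <- posterior_epred(fit, newdata)
  cbind(newdata,
        mean = rowMeans(ep),
        l66 = apply(ep, 1, quantile, 0.17, names = FALSE),
        u66 = apply(ep, 1, quantile, 0.83, names = FALSE),
        l95 = apply(ep, 1, quantile, 0.025, names = FALSE),
        u95 = apply(ep, 1, quantile, 0.975, names = FALSE))
}

#' A reference grid over chosen predictors
#'
#' Builds a full factorial grid over the `vary` predictors, holding every
#' other factor used by the fit at its reference level.
#'
#' @param fit an `rp_beta_fit`.
#' @param vary named list predictor -> values.
#' @return data frame grid.
#' @export
reference_grid <- function(fit, vary) {
  grid <- expand.grid(vary, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  for (v in names(fit$xlevels))
    if (!v %in% colnames(grid)) grid[[v]] <- fit$xlevels[[v]][1]
  used <- all.vars(fit$formula)
  for (v in setdiff(used, c(colnames(grid), "p_correct")))
    grid[[v]] <- FALSE  # logical position flags default to FALSE
  grid
}

#' Pairwise language contrasts of fitted cell means
#'
#' Draw-wise differences on the probability scale between all ordered
#' language pairs within each cell of the grid; a contrast is flagged
#' `suppressed` when less than 95% of its posterior mass lies on one side
#' of zero.
#'
#' @param fit an `rp_beta_fit`.
#' @param cells data frame with a `language` column plus the cell-defining
#'   columns (e.g. role and the two position flags).
#' @return data frame of class `rp_contrasts`.
#' @export
pairwise_language_contrasts <- function(fit, cells) {
  if (!"language" %in% colnames(cells))
    stop("cells must contain a language column", call. = FALSE)
  ep <- posterior_epred(fit, cells)
  langs <- unique(cells$language)
  othercols <- setdiff(colnames(cells), "language")
  key <- if (length(othercols))
    do.call(paste, c(cells[othercols], sep = "|")) else rep("all", nrow(cells))
  rows <- list()
  for (kk in unique(key)) {
    idx <- which(key == kk)
    for (l1 in langs) for (l2 in langs) {
      i1 <- idx[cells$language[idx] == l1]
      i2 <- idx[cells$language[idx] == l2]
      if (length(i1) != 1 || length(i2) != 1)
        stop("missing cell for languages ", l1, "/", l2, call. = FALSE)
      d <- ep[i1, ] - ep[i2, ]
      pmass <- max(mean(d > 0), mean(d < 0))
      rows[[length(rows) + 1L]] <- cbind(
        cells[i1, othercols, drop = FALSE],
        data.frame(language1 = l1, language2 = l2, mean = mean(d),
                   l95 = quantile(d, 0.025, names = FALSE),
                   u95 = quantile(d, 0.975, names = FALSE),
                   p_direction = pmass, suppressed = pmass < 0.95,
                   stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rp_contrasts", class(out))
  out
}

#' Beta regression on stimulus-level final probabilities
#'
#' Fixed effects: role crossed with the experimental condition(s);
#' by-item random intercept and slopes for role and conditions. With a
#' single item no grouping variance is identifiable: a warning is issued
#' and a fixed-effects-only model is fitted.
#'
#' @param records output of [evaluate_stimuli()] /
#'   [stimulus_final_probability()] with an `item` column.
#' @param conditions character vector of condition column names.
#' @param ... passed to [regression_spec()] (sampler settings etc.).
#' @return an `rp_beta_fit`.
#' @export
fit_stimulus_regression <- function(records, conditions, ...) {
  if (!"item" %in% colnames(records))
    stop("stimulus records need an 'item' column", call. = FALSE)
  fixed <- c("role", conditions)
  inter <- unlist(lapply(conditions, function(cc) paste("role", cc,
                                                        sep = ":")))
  single_item <- length(unique(records$item)) < 2
  if (single_item)
    warning("single stimulus item: no grouping variance identifiable; ",
            "fitting fixed effects only", call. = FALSE)
  spec <- regression_spec(fixed_terms = fixed, interactions = inter,
                          group_by = if (single_item) NULL else "item",
                          group_slopes = c("role", conditions), ...)
  records$item <- as.character(records$item)
  fit_beta_hierarchical(build_design(records, spec))
}

#' Prior predictive draws of cell means
#'
#' Samples fixed effects from their priors and returns implied cell means
#' on the probability scale; used to check that the priors are weakly
#' informative (means cover (0,1) without piling on the boundaries).
#'
#' @param design an `rp_design`.
#' @param ndraws number of prior draws.
#' @param seed integer seed.
#' @return matrix `nrow(X)` x `ndraws` of prior predictive means.
#' @export
prior_predict_cell_means <- function(design, ndraws = 500, seed = 1) {
  X <- design$X
  has_int <- colnames(X)[1] == "(Intercept)"
  with_seed(seed, {
    B <- matrix(rnorm(ncol(X) * ndraws), ncol(X), ndraws)
    if (has_int) B[1, ] <- 2.5 * stats::rt(ndraws, df = 3)
    stats::plogis(X %*% B)
  })
}
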