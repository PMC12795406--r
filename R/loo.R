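# Pareto-smoothed importance sampling, leave-one-out expected log
# pointwise predictive density, and model stacking weights.

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Generalized Pareto fit to exceedances (profile-likelihood grid with a
# weakly informative prior on the inverse-scale grid).
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30 + floor(sqrt(n))
  j <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (3 * xstar)
  b <- b[b > 0]
  k_of_b <- vapply(b, function(bb) mean(log1p(bb * x)), 0)
  L <- n * (log(b / k_of_b) - k_of_b - 1)
  w <- exp(L - logsumexp(L))
  b_hat <- sum(b * w)
  k_hat <- mean(log1p(b_hat * x))
  list(k = k_hat, sigma = k_hat / b_hat)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

#' Pareto-smoothed importance weights
#'
#' Fits a generalized Pareto distribution to the largest 20% (at most
#' `3*sqrt(S)`) of the raw importance ratios, replaces them by expected
#' order statistics of the fit, and truncates at the raw maximum.
#'
#' @param lw vector of unnormalized log importance weights.
#' @return list with `log_weights` (normalized) and the Pareto shape
#'   diagnostic `k`.
#' @export
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5 || S < 25) {
    return(list(log_weights = lw - logsumexp(lw), k = NA_real_))
  }
  ord <- order(lw)
  tail_ids <- ord[seq.int(S - M + 1, S)]
  cut <- exp(lw[ord[S - M]])
  exceed <- exp(lw[tail_ids]) - cut
  if (max(exceed) <= 0) {
    return(list(log_weights = lw - logsumexp(lw), k = NA_real_))
  }
  fit <- gpd_fit(exceed)
  p <- (seq_len(M) - 0.5) / M
  smoothed <- log(cut + qgpd(p, fit$k, fit$sigma))
  smoothed <- pmin(smoothed, 0)  # truncate at the raw maximum (max(lw)=0)
  lw[tail_ids[order(lw[tail_ids])]] <- smoothed
  list(log_weights = lw - logsumexp(lw), k = fit$k)
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' @param log_lik draws x observations pointwise log-likelihood matrix.
#' @return list of class `rp_loo`: `elpd_loo`, `pointwise` (per
#'   observation), `pareto_k` (per observation), `p_loo`.
#' @export
loo_elpd <- function(log_lik) {
  n <- ncol(log_lik)
  pointwise <- numeric(n)
  k <- numeric(n)
  for (i in seq_len(n)) {
    ps <- psis_smooth(-log_lik[, i])
    pointwise[i] <- logsumexp(ps$log_weights + log_lik[, i])
    k[i] <- ps$k
  }
  lpd <- apply(log_lik, 2, function(c_) logsumexp(c_) - log(length(c_)))
  structure(list(elpd_loo = sum(pointwise), pointwise = pointwise,
                 pareto_k = k, p_loo = sum(lpd - pointwise)),
            class = "rp_loo")
}

#' @export
print.rp_loo <- function(x, ...) {
  cat(sprintf("<rp_loo> elpd_loo = %.2f, p_loo = %.2f, max pareto_k = %.2f\n",
              x$elpd_loo, x$p_loo, max(x$pareto_k, na.rm = TRUE)))
  invisible(x)
}

#' Stacking weights from pointwise elpd contributions
#'
#' Maximizes the leave-one-out log score of the weighted predictive
#' mixture over the simplex.
#'
#' @param lpd_point observations x models matrix of pointwise elpd values.
#' @return numeric weight vector (non-negative, sums to 1).
#' @export
stacking_weights <- function(lpd_point) {
  K <- ncol(lpd_point)
  if (K == 1) return(1)
  rmax <- apply(lpd_point, 1, max)
  expl <- exp(lpd_point - rmax)
  obj <- function(a) {
    w <- exp(c(a, 0)); w <- w / sum(w)
    -sum(log(pmax(expl %*% w, 1e-300)))
  }
  fit <- stats::optim(rep(0, K - 1), obj, method = "BFGS",
                      control = list(maxit = 500))
  w <- exp(c(fit$par, 0))
  w / sum(w)
}

#' Compare fitted models by PSIS-LOO and stacking
#'
#' @param fits named list of `rp_beta_fit` objects fitted to the identical
#'   response vector.
#' @return list with `elpd` (per model), `weights` (stacking weights),
#'   `loos` (full `rp_loo` objects), `pareto_k_max`.
#' @export
compare_loo_stacking <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits", call. = FALSE)
  y0 <- fits[[1]]$y
  for (f in fits)
    if (!isTRUE(all.equal(f$y, y0)))
      stop("fits were not computed on the identical response vector",
           call. = FALSE)
  loos <- lapply(fits, function(f) loo_elpd(f$log_lik))
  lpd <- vapply(loos, function(l) l$pointwise, numeric(length(y0)))
  w <- stacking_weights(lpd)
  names(w) <- names(fits)
  list(elpd = vapply(loos, `[[`, 0, "elpd_loo"),
       weights = w, loos = loos,
       pareto_k_max = vapply(loos, function(l) max(l$pareto_k, na.rm = TRUE),
                             0))
}
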