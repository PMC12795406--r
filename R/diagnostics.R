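# Rank-normalized split-R-hat and bulk/tail effective sample size,
# following the modern recommendations for MCMC convergence assessment
# (split chains, rank normalization, Geyer's initial monotone sequence).

autocov_fft <- function(x) {
  S <- length(x)
  n2 <- 2^ceiling(log2(2 * S))
  xx <- c(x - mean(x), rep(0, n2 - S))
  f <- stats::fft(xx)
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / n2
  ac[seq_len(S)] / S
}

split_chains <- function(ch) {
  S <- nrow(ch)
  half <- floor(S / 2)
  cbind(ch[seq_len(half), , drop = FALSE],
        ch[seq.int(S - half + 1, S), , drop = FALSE])
}

rank_normalize <- function(ch) {
  r <- rank(ch, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(ch) + 1 / 4))
  matrix(z, nrow(ch), ncol(ch))
}

rhat_basic <- function(ch) {
  S <- nrow(ch); M <- ncol(ch)
  if (S < 2) return(NA_real_)
  mu <- colMeans(ch)
  W <- mean(apply(ch, 2, stats::var))
  B <- if (M > 1) S * stats::var(mu) else 0
  vp <- (S - 1) / S * W + B / S
  if (W < 1e-300) return(NA_real_)
  sqrt(vp / W)
}

ess_core <- function(ch) {
  S <- nrow(ch); M <- ncol(ch)
  if (S < 4 || anyNA(ch)) return(NA_real_)
  if (max(ch) - min(ch) < 1e-10) return(NA_real_)
  acov <- vapply(seq_len(M), function(m) autocov_fft(ch[, m]),
                 numeric(S))
  acov <- matrix(acov, S, M)
  chain_mean <- colMeans(ch)
  mean_var <- mean(acov[1, ]) * S / (S - 1)
  var_plus <- mean_var * (S - 1) / S + (if (M > 1) stats::var(chain_mean)
                                        else 0)
  if (var_plus < 1e-300) return(NA_real_)
  rho <- rep(0, S)
  rho[1] <- 1
  rho_even <- 1
  rho_odd <- 1 - (mean_var - mean(acov[2, ])) / var_plus
  rho[2] <- rho_odd
  t <- 0L
  while (t < S - 5 && !is.nan(rho_even + rho_odd) &&
         (rho_even + rho_odd) > 0) {
    t <- t + 2L
    rho_even <- 1 - (mean_var - mean(acov[t + 1, ])) / var_plus
    rho_odd <- if (t + 2 <= S) 1 - (mean_var - mean(acov[t + 2, ])) /
      var_plus else 0
    if ((rho_even + rho_odd) >= 0) {
      rho[t + 1] <- rho_even
      if (t + 2 <= S) rho[t + 2] <- rho_odd
    }
  }
  max_t <- t
  # enforce monotone decreasing pair sums (Geyer)
  if (max_t >= 4) {
    for (tt in seq(3, max_t - 1, by = 2)) {
      if (rho[tt + 1] + rho[tt + 2] > rho[tt - 1] + rho[tt]) {
        rho[tt + 1] <- (rho[tt - 1] + rho[tt]) / 2
        rho[tt + 2] <- rho[tt + 1]
      }
    }
  }
  tau <- -1 + 2 * sum(rho[seq_len(max(1, max_t))]) + rho[max_t + 1]
  tau <- max(tau, 1 / log10(S * M + 10))
  ess <- S * M / tau
  min(ess, S * M * log10(S * M))
}

#' Split-R-hat of one parameter
#'
#' Maximum of the rank-normalized split-R-hat of the draws and of the
#' folded draws (absolute deviations from the median), so both location
#' and scale non-mixing are detected.
#'
#' @param ch draws matrix, iterations x chains.
#' @return scalar R-hat (NA for constant draws).
#' @export
rhat <- function(ch) {
  ch <- as.matrix(ch)
  if (max(ch) - min(ch) < 1e-10) return(NA_real_)
  bulk <- rhat_basic(rank_normalize(split_chains(ch)))
  folded <- rhat_basic(rank_normalize(split_chains(abs(ch - stats::median(ch)))))
  max(bulk, folded)
}

#' Bulk and tail effective sample size
#'
#' @param ch draws matrix, iterations x chains.
#' @return scalar ESS.
#' @export
ess_bulk <- function(ch) {
  ch <- as.matrix(ch)
  ess_core(rank_normalize(split_chains(ch)))
}

#' @rdname ess_bulk
#' @export
ess_tail <- function(ch) {
  ch <- as.matrix(ch)
  q <- stats::quantile(ch, c(0.05, 0.95), names = FALSE)
  e1 <- ess_core(split_chains(matrix(as.numeric(ch <= q[1]), nrow(ch))))
  e2 <- ess_core(split_chains(matrix(as.numeric(ch >= q[2]), nrow(ch))))
  min(e1, e2, na.rm = TRUE)
}

# diagnostics table for a draws array (iterations x chains x params)
mcmc_diagnostics <- function(arr, par_names) {
  out <- data.frame(parameter = par_names,
                    rhat = NA_real_, ess_bulk = NA_real_,
                    ess_tail = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_along(par_names)) {
    ch <- arr[, , j, drop = TRUE]
    ch <- as.matrix(ch)
    out$rhat[j] <- rhat(ch)
    out$ess_bulk[j] <- ess_bulk(ch)
    out$ess_tail[j] <- ess_tail(ch)
  }
  out
}
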