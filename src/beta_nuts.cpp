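// Hierarchical beta regression (logit link for the mean, log link for the
// precision) with non-centered group effects, and a No-U-Turn sampler with
// multinomial proposal sampling, dual-averaging step-size adaptation and a
// windowed diagonal metric. RNG comes from R's stream, so chains are fully
// reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// fast digamma: recurrence to x >= 6 then asymptotic series
static inline double digamma_fast(double x) {
  double r = 0.0;
  while (x < 6.0) { r -= 1.0 / x; x += 1.0; }
  double f = 1.0 / (x * x);
  return r + std::log(x) - 0.5 / x -
         f * (1.0 / 12.0 -
              f * (1.0 / 120.0 -
                   f * (1.0 / 252.0 - f * (1.0 / 240.0 - f / 132.0))));
}

struct BetaModel {
  const vec& y;
  const mat& X;      // n x p fixed-effect design
  const mat& R;      // n x q random-effect design (q may be 0)
  const uvec& g;     // 0-based group index per row
  int G;             // number of groups
  int phi_prior;     // 0 = Half-Normal(0,10), 1 = Exponential(1)
  bool intercept;    // first beta column gets the Student-t(3,0,2.5) prior
  vec logy, log1my;

  int p() const { return X.n_cols; }
  int q() const { return R.n_cols; }
  int dim() const { return p() + q() * G + q() + 1; }

  BetaModel(const vec& y_, const mat& X_, const mat& R_, const uvec& g_,
            int G_, int phi_prior_, bool intercept_)
    : y(y_), X(X_), R(R_), g(g_), G(G_), phi_prior(phi_prior_),
      intercept(intercept_) {
    logy = log(y);
    log1my = log(1.0 - y);
  }

  // th = [beta(p), z(q*G, column per group), log_sigma(q), log_phi]
  double logpost(const vec& th, vec& grad, bool want_grad) const {
    int n = y.n_elem, P = p(), Q = q();
    vec beta = th.subvec(0, P - 1);
    mat z;
    vec sigma, log_sigma;
    if (Q > 0) {
      z = reshape(th.subvec(P, P + Q * G - 1), Q, G);
      log_sigma = th.subvec(P + Q * G, P + Q * G + Q - 1);
      sigma = exp(log_sigma);
    }
    double log_phi = th[th.n_elem - 1];
    double phi = std::exp(log_phi);

    vec eta = X * beta;
    if (Q > 0)
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < Q; ++j)
          eta[i] += R(i, j) * sigma[j] * z(j, g[i]);

    double lp = 0, dphi_acc = 0;
    const double lgam_phi = std::lgamma(phi);
    const double digam_phi = digamma_fast(phi);
    vec deta(n);
    for (int i = 0; i < n; ++i) {
      double mu = 1.0 / (1.0 + std::exp(-eta[i]));
      mu = std::min(1.0 - 1e-12, std::max(1e-12, mu));
      double a = mu * phi, b = (1.0 - mu) * phi;
      lp += lgam_phi - std::lgamma(a) - std::lgamma(b)
          + (a - 1.0) * logy[i] + (b - 1.0) * log1my[i];
      if (want_grad) {
        double da = digamma_fast(a), db = digamma_fast(b);
        deta[i] = phi * mu * (1.0 - mu) * (-da + db + logy[i] - log1my[i]);
        dphi_acc += digam_phi - mu * da - (1.0 - mu) * db
                  + mu * logy[i] + (1.0 - mu) * log1my[i];
      }
    }

    if (want_grad) grad.zeros(th.n_elem);

    // priors on beta: N(0,1) slopes, Student-t(3, 0, 2.5) intercept
    for (int j = 0; j < P; ++j) {
      double bj = beta[j];
      if (intercept && j == 0) {
        lp += -2.0 * std::log1p(bj * bj / 18.75);
        if (want_grad) grad[j] += -4.0 * bj / (18.75 + bj * bj);
      } else {
        lp += -0.5 * bj * bj;
        if (want_grad) grad[j] += -bj;
      }
    }

    if (Q > 0) {
      // z ~ N(0,1)
      lp += -0.5 * accu(z % z);
      // sigma ~ Half-t(3, 0, 2.5), sampled as log_sigma (+ Jacobian)
      for (int j = 0; j < Q; ++j) {
        double s = sigma[j];
        lp += -2.0 * std::log1p(s * s / 18.75) + log_sigma[j];
        if (want_grad)
          grad[P + Q * G + j] += s * (-4.0 * s / (18.75 + s * s)) + 1.0;
      }
    }

    // phi prior (+ Jacobian of the log transform)
    double dphi_pr;
    if (phi_prior == 0) { lp += -phi * phi / 200.0; dphi_pr = -phi / 100.0; }
    else { lp += -phi; dphi_pr = -1.0; }
    lp += log_phi;

    if (want_grad) {
      grad.subvec(0, P - 1) += X.t() * deta;
      if (Q > 0) {
        for (int i = 0; i < n; ++i)
          for (int j = 0; j < Q; ++j) {
            grad[P + g[i] * Q + j] += R(i, j) * sigma[j] * deta[i];
            grad[P + Q * G + j] += deta[i] * R(i, j) * z(j, g[i]) * sigma[j];
          }
        grad.subvec(P, P + Q * G - 1) +=
          -vectorise(z);  // z prior gradient
      }
      grad[th.n_elem - 1] = phi * (dphi_acc + dphi_pr) + 1.0;
    }
    return lp;
  }
};

struct PhasePoint {
  vec th, r, grad;
  double lp;
};

struct NutsTree {
  PhasePoint minus, plus;
  vec th_prop;
  vec rho;  // summed momentum over the subtree
  double log_sum_w;
  double sum_alpha;
  int n_alpha;
  bool valid;
  bool divergent;
};

class Nuts {
public:
  const BetaModel& M;
  vec inv_metric;
  double eps;
  int max_depth = 10;
  int divergences = 0;

  Nuts(const BetaModel& m) : M(m) {
    inv_metric.ones(m.dim());
    eps = 0.1;
  }

  double kinetic(const vec& r) const {
    return 0.5 * dot(r, inv_metric % r);
  }

  void leapfrog(PhasePoint& z, double dir) const {
    double e = dir * eps;
    z.r += 0.5 * e * z.grad;
    z.th += e * (inv_metric % z.r);
    z.lp = M.logpost(z.th, z.grad, true);
    z.r += 0.5 * e * z.grad;
  }

  // generalized no-u-turn criterion on the summed momentum
  bool uturn(const vec& rho, const PhasePoint& minus,
             const PhasePoint& plus) const {
    return dot(rho, inv_metric % minus.r) < 0 ||
           dot(rho, inv_metric % plus.r) < 0;
  }

  NutsTree build_tree(int depth, PhasePoint z, double dir, double H0) {
    if (depth == 0) {
      leapfrog(z, dir);
      double H = z.lp - kinetic(z.r);
      double dH = H - H0;
      NutsTree t;
      t.minus = z; t.plus = z; t.th_prop = z.th;
      t.rho = z.r;
      t.divergent = !std::isfinite(dH) || dH < -1000.0;
      t.valid = !t.divergent;
      t.log_sum_w = t.divergent ? -datum::inf : dH;
      t.sum_alpha = std::isfinite(dH) ? std::min(1.0, std::exp(dH)) : 0.0;
      t.n_alpha = 1;
      if (t.divergent) ++divergences;
      return t;
    }
    NutsTree left = build_tree(depth - 1, z, dir, H0);
    if (!left.valid) return left;
    NutsTree right = build_tree(depth - 1, dir > 0 ? left.plus : left.minus,
                                dir, H0);
    NutsTree t;
    t.minus = dir > 0 ? left.minus : right.minus;
    t.plus = dir > 0 ? right.plus : left.plus;
    t.log_sum_w = std::max(left.log_sum_w, right.log_sum_w) +
      std::log(std::exp(left.log_sum_w -
                        std::max(left.log_sum_w, right.log_sum_w)) +
               std::exp(right.log_sum_w -
                        std::max(left.log_sum_w, right.log_sum_w)));
    double p_right = std::exp(right.log_sum_w - t.log_sum_w);
    t.th_prop = (R::unif_rand() < p_right) ? right.th_prop : left.th_prop;
    t.sum_alpha = left.sum_alpha + right.sum_alpha;
    t.n_alpha = left.n_alpha + right.n_alpha;
    t.divergent = right.divergent;
    t.rho = left.rho + right.rho;
    // full-subtree check plus the two cross-subtree checks
    bool ok = !uturn(t.rho, t.minus, t.plus);
    if (ok) {
      const NutsTree& first = dir > 0 ? left : right;
      const NutsTree& second = dir > 0 ? right : left;
      vec rho_x1 = first.rho + second.minus.r;
      ok = ok && !uturn(rho_x1, t.minus, second.minus);
      vec rho_x2 = second.rho + first.plus.r;
      ok = ok && !uturn(rho_x2, first.plus, t.plus);
    }
    t.valid = right.valid && ok;
    return t;
  }

  // one NUTS transition; returns average acceptance statistic
  double transition(vec& th) {
    PhasePoint z;
    z.th = th;
    z.lp = M.logpost(z.th, z.grad, true);
    z.r.set_size(th.n_elem);
    for (size_t j = 0; j < th.n_elem; ++j)
      z.r[j] = norm_rand() / std::sqrt(inv_metric[j]);
    double H0 = z.lp - kinetic(z.r);

    PhasePoint zminus = z, zplus = z;
    vec th_prop = z.th;
    vec rho = z.r;
    double log_sum_w = 0.0;
    double sum_alpha = 0.0;
    int n_alpha = 0;

    for (int depth = 0; depth < max_depth; ++depth) {
      double dir = (R::unif_rand() < 0.5) ? -1.0 : 1.0;
      NutsTree sub = build_tree(depth, dir > 0 ? zplus : zminus, dir, H0);
      sum_alpha += sub.sum_alpha;
      n_alpha += sub.n_alpha;
      if (!sub.valid) break;
      // biased progressive sampling: favor the newly built subtree
      double p_new = std::exp(sub.log_sum_w - log_sum_w);
      if (R::unif_rand() < p_new) th_prop = sub.th_prop;
      log_sum_w = std::max(log_sum_w, sub.log_sum_w) +
        std::log(std::exp(log_sum_w - std::max(log_sum_w, sub.log_sum_w)) +
                 std::exp(sub.log_sum_w -
                          std::max(log_sum_w, sub.log_sum_w)));
      if (dir > 0) zplus = sub.plus; else zminus = sub.minus;
      rho += sub.rho;
      if (uturn(rho, zminus, zplus)) break;
    }
    th = th_prop;
    return n_alpha > 0 ? sum_alpha / n_alpha : 0.0;
  }

  void init_stepsize(const vec& th0) {
    PhasePoint z;
    z.th = th0;
    z.lp = M.logpost(z.th, z.grad, true);
    z.r.set_size(th0.n_elem);
    for (size_t j = 0; j < th0.n_elem; ++j)
      z.r[j] = norm_rand() / std::sqrt(inv_metric[j]);
    double H0 = z.lp - kinetic(z.r);
    PhasePoint zt = z;
    leapfrog(zt, 1.0);
    double dH = (zt.lp - kinetic(zt.r)) - H0;
    if (!std::isfinite(dH)) dH = -datum::inf;
    double dir = dH > std::log(0.5) ? 1.0 : -1.0;
    for (int it = 0; it < 50; ++it) {
      eps *= dir > 0 ? 2.0 : 0.5;
      zt = z;
      leapfrog(zt, 1.0);
      dH = (zt.lp - kinetic(zt.r)) - H0;
      if (!std::isfinite(dH)) dH = -datum::inf;
      if (dir > 0 ? (dH <= std::log(0.5)) : (dH >= std::log(0.5))) break;
    }
  }
};

// [[Rcpp::export]]
Rcpp::List cpp_beta_nuts(const arma::vec& y, const arma::mat& X,
                         const arma::mat& R_, const arma::uvec& g, int G,
                         int phi_prior, bool intercept,
                         const arma::vec& init, int warmup, int iter,
                         double target_accept, int max_depth) {
  BetaModel M(y, X, R_, g, G, phi_prior, intercept);
  Nuts S(M);
  S.max_depth = max_depth;
  int D = M.dim();
  if ((int)init.n_elem != D) Rcpp::stop("init length != %d", D);
  Rcpp::RNGScope scope;

  vec th = init;
  S.init_stepsize(th);

  // dual averaging
  double mu = std::log(10.0 * S.eps), log_eps_bar = 0.0, Hbar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_t = 0;

  // expanding metric-adaptation windows (Stan-style): an initial
  // step-size-only buffer, doubling covariance windows, a terminal buffer
  int init_buf = std::min(75, warmup / 5);
  int term_buf = std::min(50, warmup / 5);
  std::vector<int> window_ends;
  {
    int wsize = 25, pos = init_buf;
    while (pos < warmup - term_buf) {
      int end = pos + wsize;
      if (end + 2 * wsize > warmup - term_buf) end = warmup - term_buf;
      window_ends.push_back(end);
      pos = end;
      wsize *= 2;
    }
  }
  size_t cur_win = 0;
  mat window(D, warmup > 0 ? warmup : 1);
  int w_n = 0;

  mat draws(iter, D);
  vec lp_out(iter), accept_out(iter);

  for (int s = 0; s < warmup + iter; ++s) {
    double alpha = S.transition(th);
    bool adapting = s < warmup;
    if (adapting) {
      ++da_t;
      Hbar = (1.0 - 1.0 / (da_t + t0)) * Hbar +
             (target_accept - alpha) / (da_t + t0);
      double log_eps = mu - std::sqrt((double)da_t) / gamma * Hbar;
      double w = std::pow((double)da_t, -kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      S.eps = std::exp(log_eps);
      if (cur_win < window_ends.size() && s >= init_buf)
        window.col(w_n++) = th;
      if (cur_win < window_ends.size() && s == window_ends[cur_win] - 1) {
        if (w_n > 10) {
          vec v = var(window.cols(0, w_n - 1), 0, 1);
          double reg = 5.0 / (w_n + 5.0);
          S.inv_metric = (1.0 - reg) * v + reg * 1e-3 * ones(D);
          S.init_stepsize(th);
          mu = std::log(10.0 * S.eps);
          Hbar = 0.0; log_eps_bar = std::log(S.eps); da_t = 0;
        }
        w_n = 0;
        ++cur_win;
      }
      if (s == warmup - 1) {
        S.eps = std::exp(log_eps_bar);
        S.divergences = 0;  // report post-warmup divergences only
      }
    } else {
      int k = s - warmup;
      draws.row(k) = th.t();
      vec dummy;
      lp_out[k] = M.logpost(th, dummy, false);
      accept_out[k] = alpha;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("draws") = draws,
    Rcpp::Named("lp") = lp_out,
    Rcpp::Named("accept_stat") = accept_out,
    Rcpp::Named("stepsize") = S.eps,
    Rcpp::Named("divergences") = S.divergences);
}

// pointwise log-likelihood matrix (draws x observations) for LOO
// [[Rcpp::export]]
arma::mat cpp_beta_loglik(const arma::vec& y, const arma::mat& X,
                          const arma::mat& R_, const arma::uvec& g, int G,
                          const arma::mat& draws) {
  int n = y.n_elem, S = draws.n_rows, P = X.n_cols, Q = R_.n_cols;
  vec logy = log(y), log1my = log(1.0 - y);
  mat out(S, n);
  for (int s = 0; s < S; ++s) {
    vec th = draws.row(s).t();
    vec beta = th.subvec(0, P - 1);
    mat z; vec sigma;
    if (Q > 0) {
      z = reshape(th.subvec(P, P + Q * G - 1), Q, G);
      sigma = exp(th.subvec(P + Q * G, P + Q * G + Q - 1));
    }
    double phi = std::exp(th[th.n_elem - 1]);
    double lgam_phi = std::lgamma(phi);
    vec eta = X * beta;
    for (int i = 0; i < n; ++i) {
      if (Q > 0)
        for (int j = 0; j < Q; ++j) eta[i] += R_(i, j) * sigma[j] * z(j, g[i]);
      double m = 1.0 / (1.0 + std::exp(-eta[i]));
      m = std::min(1.0 - 1e-12, std::max(1e-12, m));
      double a = m * phi, b = (1.0 - m) * phi;
      out(s, i) = lgam_phi - std::lgamma(a) - std::lgamma(b)
                + (a - 1.0) * logy[i] + (b - 1.0) * log1my[i];
    }
  }
  return out;
}
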