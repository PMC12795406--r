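// Incremental semantic role prediction model: token embeddings, an LSTM
// sequential encoder that reduces multi-token argument spans to one vector,
// an LSTM sentence processor over elements, a one-hidden-layer role
// classifier fed [argument encoding; processor state; verb encoding-or-zeros]
// and a one-hidden-layer next-word predictor. Forward and full
// backpropagation-through-time are implemented by hand; the R side owns
// parameter initialization and the Adam update, so every exported function
// here is a pure function of (params, data).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Dims {
  int V, d, He, Hp, Hc, Din;
  // offsets into the flat parameter vector
  size_t oEmb, oWxe, oWhe, obe, oWxp, oWhp, obp,
         oW1n, ob1n, oW2n, ob2n, oW1r, ob1r, oW2r, ob2r, total;
};

static Dims make_dims(const Rcpp::IntegerVector& dv) {
  Dims D;
  D.V = dv[0]; D.d = dv[1]; D.He = dv[2]; D.Hp = dv[3]; D.Hc = dv[4];
  D.Din = 2 * D.He + D.Hp;
  size_t o = 0;
  D.oEmb = o; o += (size_t)D.d * D.V;
  D.oWxe = o; o += (size_t)4 * D.He * D.d;
  D.oWhe = o; o += (size_t)4 * D.He * D.He;
  D.obe  = o; o += (size_t)4 * D.He;
  D.oWxp = o; o += (size_t)4 * D.Hp * D.He;
  D.oWhp = o; o += (size_t)4 * D.Hp * D.Hp;
  D.obp  = o; o += (size_t)4 * D.Hp;
  D.oW1n = o; o += (size_t)D.Hc * D.Hp;
  D.ob1n = o; o += (size_t)D.Hc;
  D.oW2n = o; o += (size_t)D.V * D.Hc;
  D.ob2n = o; o += (size_t)D.V;
  D.oW1r = o; o += (size_t)D.Hc * D.Din;
  D.ob1r = o; o += (size_t)D.Hc;
  D.oW2r = o; o += (size_t)2 * D.Hc;
  D.ob2r = o; o += (size_t)2;
  D.total = o;
  return D;
}

// read-only matrix view into the parameter vector
static mat view(const vec& p, size_t off, int nr, int nc) {
  return mat(const_cast<double*>(p.memptr()) + off, nr, nc, false, true);
}
static mat gview(vec& g, size_t off, int nr, int nc) {
  return mat(g.memptr() + off, nr, nc, false, true);
}

// [[Rcpp::export]]
int cpp_srp_param_count(Rcpp::IntegerVector dims) {
  return (int)make_dims(dims).total;
}

struct LstmCache {
  std::vector<vec> x, hprev, cprev, i, f, g, o, c, tc;
  vec h_final;
};

// run an LSTM over the columns of X; returns cache for backward
static LstmCache lstm_forward(const mat& Wx, const mat& Wh, const vec& b,
                              const mat& X, int H) {
  LstmCache C;
  vec h(H, fill::zeros), c(H, fill::zeros);
  int T = X.n_cols;
  for (int t = 0; t < T; ++t) {
    vec x = X.col(t);
    vec z = Wx * x + Wh * h + b;
    vec i = 1.0 / (1.0 + exp(-z.subvec(0, H - 1)));
    vec f = 1.0 / (1.0 + exp(-z.subvec(H, 2 * H - 1)));
    vec g = tanh(z.subvec(2 * H, 3 * H - 1));
    vec o = 1.0 / (1.0 + exp(-z.subvec(3 * H, 4 * H - 1)));
    C.x.push_back(x); C.hprev.push_back(h); C.cprev.push_back(c);
    c = f % c + i % g;
    vec tc = tanh(c);
    h = o % tc;
    C.i.push_back(i); C.f.push_back(f); C.g.push_back(g); C.o.push_back(o);
    C.c.push_back(c); C.tc.push_back(tc);
  }
  C.h_final = h;
  return C;
}

// backward through one LSTM given per-step external gradients on h.
// dX receives gradients on the inputs (same shape as X).
static void lstm_backward(const mat& Wx, const mat& Wh,
                          const LstmCache& C, const mat& dh_ext,
                          mat& gWx, mat& gWh, vec& gb, mat& dX) {
  int H = Wh.n_cols;
  int T = C.x.size();
  vec dh(H, fill::zeros), dc(H, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    dh += dh_ext.col(t);
    const vec &i = C.i[t], &f = C.f[t], &g = C.g[t], &o = C.o[t],
              &tc = C.tc[t];
    vec do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    vec di = dc % g;
    vec df = dc % C.cprev[t];
    vec dg = dc % i;
    vec dc_prev = dc % f;
    vec dz(4 * H);
    dz.subvec(0, H - 1)         = di % i % (1.0 - i);
    dz.subvec(H, 2 * H - 1)     = df % f % (1.0 - f);
    dz.subvec(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    dz.subvec(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    gWx += dz * C.x[t].t();
    gWh += dz * C.hprev[t].t();
    gb += dz;
    dX.col(t) = Wx.t() * dz;
    dh = Wh.t() * dz;
    dc = dc_prev;
  }
}

static vec softmax(const vec& z) {
  vec e = exp(z - z.max());
  return e / accu(e);
}

struct Utt {
  std::vector<uvec> elements;  // 0-based token ids per element
  uvec args;                   // 0-based element indices of arguments
  uvec roles;                  // 0 = A, 1 = P
  int verb;                    // 0-based element index of the verb, or -1
  uvec nw;                     // 0-based next-token target per element
};

static Utt parse_utt(const Rcpp::List& u) {
  Utt x;
  Rcpp::List els = u["elements"];
  for (int j = 0; j < els.size(); ++j) {
    Rcpp::IntegerVector tv = els[j];
    uvec ids(tv.size());
    for (int k = 0; k < tv.size(); ++k) ids[k] = tv[k] - 1;
    x.elements.push_back(ids);
  }
  Rcpp::IntegerVector av = u["args"], rv = u["roles"], nw = u["nw"];
  x.args.set_size(av.size());
  x.roles.set_size(rv.size());
  for (int k = 0; k < av.size(); ++k) { x.args[k] = av[k] - 1; x.roles[k] = rv[k] - 1; }
  x.verb = Rcpp::as<int>(u["verb"]) - 1;
  x.nw.set_size(nw.size());
  for (int k = 0; k < nw.size(); ++k) x.nw[k] = nw[k] - 1;
  return x;
}

struct FwdState {
  std::vector<LstmCache> encCaches;  // one per element
  std::vector<mat> encX;             // token embedding matrices per element
  LstmCache procCache;               // over element encodings
  mat enc;                           // He x T element encodings
  mat hp;                            // Hp x T processor states
};

static void forward_core(const vec& p, const Dims& D, const Utt& u,
                         FwdState& S) {
  mat Emb = view(p, D.oEmb, D.d, D.V);
  mat Wxe = view(p, D.oWxe, 4 * D.He, D.d);
  mat Whe = view(p, D.oWhe, 4 * D.He, D.He);
  vec be(const_cast<double*>(p.memptr()) + D.obe, 4 * D.He, false, true);
  mat Wxp = view(p, D.oWxp, 4 * D.Hp, D.He);
  mat Whp = view(p, D.oWhp, 4 * D.Hp, D.Hp);
  vec bp(const_cast<double*>(p.memptr()) + D.obp, 4 * D.Hp, false, true);

  int T = u.elements.size();
  S.enc.set_size(D.He, T);
  for (int t = 0; t < T; ++t) {
    const uvec& ids = u.elements[t];
    mat X(D.d, ids.n_elem);
    for (size_t k = 0; k < ids.n_elem; ++k) X.col(k) = Emb.col(ids[k]);
    S.encX.push_back(X);
    S.encCaches.push_back(lstm_forward(Wxe, Whe, be, X, D.He));
    S.enc.col(t) = S.encCaches.back().h_final;
  }
  S.procCache = lstm_forward(Wxp, Whp, bp, S.enc, D.Hp);
  S.hp.set_size(D.Hp, T);
  for (int t = 0; t < T; ++t) {
    // reconstruct h_t from cache: h_t = o_t % tanh(c_t)
    S.hp.col(t) = S.procCache.o[t] % S.procCache.tc[t];
  }
}

// role classifier input for argument j at time t
static vec role_input(const Dims& D, const FwdState& S, const Utt& u,
                      int argElem, int t) {
  vec xin(D.Din, fill::zeros);
  xin.subvec(0, D.He - 1) = S.enc.col(argElem);
  xin.subvec(D.He, D.He + D.Hp - 1) = S.hp.col(t);
  if (u.verb >= 0 && u.verb <= t)
    xin.subvec(D.He + D.Hp, D.Din - 1) = S.enc.col(u.verb);
  return xin;
}

// [[Rcpp::export]]
Rcpp::List cpp_srp_loss_grad(const arma::vec& params,
                             Rcpp::IntegerVector dims,
                             Rcpp::List utts, double lambda, int stage,
                             bool want_grad) {
  Dims D = make_dims(dims);
  if (params.n_elem != D.total) Rcpp::stop("parameter vector length mismatch");
  mat W1n = view(params, D.oW1n, D.Hc, D.Hp);
  vec b1n(const_cast<double*>(params.memptr()) + D.ob1n, D.Hc, false, true);
  mat W2n = view(params, D.oW2n, D.V, D.Hc);
  vec b2n(const_cast<double*>(params.memptr()) + D.ob2n, D.V, false, true);
  mat W1r = view(params, D.oW1r, D.Hc, D.Din);
  vec b1r(const_cast<double*>(params.memptr()) + D.ob1r, D.Hc, false, true);
  mat W2r = view(params, D.oW2r, 2, D.Hc);
  vec b2r(const_cast<double*>(params.memptr()) + D.ob2r, 2, false, true);
  mat Wxe = view(params, D.oWxe, 4 * D.He, D.d);
  mat Whe = view(params, D.oWhe, 4 * D.He, D.He);
  mat Wxp = view(params, D.oWxp, 4 * D.Hp, D.He);
  mat Whp = view(params, D.oWhp, 4 * D.Hp, D.Hp);

  vec grad;
  if (want_grad) grad = vec(D.total, fill::zeros);

  double loss = 0, nw_loss_tot = 0, role_loss_tot = 0;
  int n_role = 0, n_correct = 0;

  for (int ui = 0; ui < utts.size(); ++ui) {
    Utt u = parse_utt(utts[ui]);
    int T = u.elements.size();
    FwdState S;
    forward_core(params, D, u, S);

    mat dhp_ext(D.Hp, T, fill::zeros);
    mat denc_ext(D.He, T, fill::zeros);

    // next-word loss at each position
    double nw_loss = 0;
    std::vector<vec> nw_hid(T), nw_p(T);
    for (int t = 0; t < T; ++t) {
      vec hid = tanh(W1n * S.hp.col(t) + b1n);
      vec pr = softmax(W2n * hid + b2n);
      nw_hid[t] = hid; nw_p[t] = pr;
      nw_loss += -std::log(std::max(pr[u.nw[t]], 1e-300));
    }
    nw_loss /= T;

    // role loss at the final position (main stage only)
    double role_loss = 0;
    std::vector<vec> r_hid(u.args.n_elem), r_p(u.args.n_elem),
                     r_xin(u.args.n_elem);
    if (stage == 1) {
      for (size_t j = 0; j < u.args.n_elem; ++j) {
        vec xin = role_input(D, S, u, u.args[j], T - 1);
        vec hid = tanh(W1r * xin + b1r);
        vec pr = softmax(W2r * hid + b2r);
        r_xin[j] = xin; r_hid[j] = hid; r_p[j] = pr;
        role_loss += -std::log(std::max(pr[u.roles[j]], 1e-300));
        ++n_role;
        if ((pr[0] >= pr[1]) == (u.roles[j] == 0)) ++n_correct;
      }
    }

    double nw_w = (stage == 1) ? lambda : 1.0;
    loss += nw_w * nw_loss + role_loss;
    nw_loss_tot += nw_loss;
    role_loss_tot += role_loss;

    if (!want_grad) continue;

    mat gW1n = gview(grad, D.oW1n, D.Hc, D.Hp);
    vec gb1n(grad.memptr() + D.ob1n, D.Hc, false, true);
    mat gW2n = gview(grad, D.oW2n, D.V, D.Hc);
    vec gb2n(grad.memptr() + D.ob2n, D.V, false, true);
    mat gW1r = gview(grad, D.oW1r, D.Hc, D.Din);
    vec gb1r(grad.memptr() + D.ob1r, D.Hc, false, true);
    mat gW2r = gview(grad, D.oW2r, 2, D.Hc);
    vec gb2r(grad.memptr() + D.ob2r, 2, false, true);
    mat gWxe = gview(grad, D.oWxe, 4 * D.He, D.d);
    mat gWhe = gview(grad, D.oWhe, 4 * D.He, D.He);
    vec gbe(grad.memptr() + D.obe, 4 * D.He, false, true);
    mat gWxp = gview(grad, D.oWxp, 4 * D.Hp, D.He);
    mat gWhp = gview(grad, D.oWhp, 4 * D.Hp, D.Hp);
    vec gbp(grad.memptr() + D.obp, 4 * D.Hp, false, true);
    mat gEmb = gview(grad, D.oEmb, D.d, D.V);

    // next-word gradients
    for (int t = 0; t < T; ++t) {
      vec dlog = nw_p[t];
      dlog[u.nw[t]] -= 1.0;
      dlog *= nw_w / T;
      gW2n += dlog * nw_hid[t].t();
      gb2n += dlog;
      vec dhid = W2n.t() * dlog;
      vec dpre = dhid % (1.0 - nw_hid[t] % nw_hid[t]);
      gW1n += dpre * S.hp.col(t).t();
      gb1n += dpre;
      dhp_ext.col(t) += W1n.t() * dpre;
    }

    // role classifier gradients (final position)
    if (stage == 1) {
      for (size_t j = 0; j < u.args.n_elem; ++j) {
        vec dlog = r_p[j];
        dlog[u.roles[j]] -= 1.0;
        gW2r += dlog * r_hid[j].t();
        gb2r += dlog;
        vec dhid = W2r.t() * dlog;
        vec dpre = dhid % (1.0 - r_hid[j] % r_hid[j]);
        gW1r += dpre * r_xin[j].t();
        gb1r += dpre;
        vec dxin = W1r.t() * dpre;
        denc_ext.col(u.args[j]) += dxin.subvec(0, D.He - 1);
        dhp_ext.col(T - 1) += dxin.subvec(D.He, D.He + D.Hp - 1);
        if (u.verb >= 0)  // verb always precedes final position read-off
          denc_ext.col(u.verb) += dxin.subvec(D.He + D.Hp, D.Din - 1);
      }
    }

    // processor BPTT -> gradients on element encodings
    mat dEnc(D.He, T, fill::zeros);
    lstm_backward(Wxp, Whp, S.procCache, dhp_ext, gWxp, gWhp, gbp, dEnc);
    dEnc += denc_ext;

    // encoder BPTT per element -> embedding gradients
    for (int t = 0; t < T; ++t) {
      int m = u.elements[t].n_elem;
      mat dh_ext(D.He, m, fill::zeros);
      dh_ext.col(m - 1) = dEnc.col(t);
      mat dX(D.d, m, fill::zeros);
      lstm_backward(Wxe, Whe, S.encCaches[t], dh_ext, gWxe, gWhe, gbe, dX);
      for (int k = 0; k < m; ++k) gEmb.col(u.elements[t][k]) += dX.col(k);
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("nw_loss") = nw_loss_tot,
    Rcpp::Named("role_loss") = role_loss_tot,
    Rcpp::Named("n_role") = n_role,
    Rcpp::Named("n_correct") = n_correct);
  if (want_grad) out["grad"] = grad;
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_srp_forward(const arma::vec& params, Rcpp::IntegerVector dims,
                           Rcpp::List utt, bool want_nextword) {
  Dims D = make_dims(dims);
  if (params.n_elem != D.total) Rcpp::stop("parameter vector length mismatch");
  Utt u = parse_utt(utt);
  int T = u.elements.size();
  FwdState S;
  forward_core(params, D, u, S);

  mat W1r = view(params, D.oW1r, D.Hc, D.Din);
  vec b1r(const_cast<double*>(params.memptr()) + D.ob1r, D.Hc, false, true);
  mat W2r = view(params, D.oW2r, 2, D.Hc);
  vec b2r(const_cast<double*>(params.memptr()) + D.ob2r, 2, false, true);

  int nA = u.args.n_elem;
  mat probA(nA, T);
  probA.fill(datum::nan);
  for (int t = 0; t < T; ++t)
    for (int j = 0; j < nA; ++j) {
      if ((int)u.args[j] > t) continue;
      vec pr = softmax(W2r * tanh(W1r * role_input(D, S, u, u.args[j], t) + b1r)
                       + b2r);
      probA(j, t) = pr[0];
    }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("probA") = probA,
    Rcpp::Named("n_elements") = T);
  if (want_nextword) {
    mat W1n = view(params, D.oW1n, D.Hc, D.Hp);
    vec b1n(const_cast<double*>(params.memptr()) + D.ob1n, D.Hc, false, true);
    mat W2n = view(params, D.oW2n, D.V, D.Hc);
    vec b2n(const_cast<double*>(params.memptr()) + D.ob2n, D.V, false, true);
    mat nw(D.V, T);
    for (int t = 0; t < T; ++t)
      nw.col(t) = softmax(W2n * tanh(W1n * S.hp.col(t) + b1n) + b2n);
    out["nextword"] = nw;
  }
  return out;
}

// encoder representation of one element (argument span or single token)
// [[Rcpp::export]]
arma::vec cpp_srp_encode(const arma::vec& params, Rcpp::IntegerVector dims,
                         Rcpp::IntegerVector token_ids) {
  Dims D = make_dims(dims);
  if (params.n_elem != D.total) Rcpp::stop("parameter vector length mismatch");
  mat Emb = view(params, D.oEmb, D.d, D.V);
  mat Wxe = view(params, D.oWxe, 4 * D.He, D.d);
  mat Whe = view(params, D.oWhe, 4 * D.He, D.He);
  vec be(const_cast<double*>(params.memptr()) + D.obe, 4 * D.He, false, true);
  mat X(D.d, token_ids.size());
  for (int k = 0; k < token_ids.size(); ++k)
    X.col(k) = Emb.col(token_ids[k] - 1);
  return lstm_forward(Wxe, Whe, be, X, D.He).h_final;
}
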