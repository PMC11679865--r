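// Two-layer LSTM classifier with additive attention, batch normalization,
// dropout and an Adam training loop.
//
// Layout conventions:
//   * minibatch cube X: (examples B) x (input features) x (timesteps T);
//     slice t is the B x features matrix at time t.
//   * LSTM weights are stored gate-concatenated: W (in x 4H), U (H x 4H),
//     bias (1 x 4H), gate column order [input | forget | candidate | output].
//     The candidate gate has its own parameters (the standard cell).
//   * All randomness (dropout masks, shuffling) comes from R's RNG so a
//     single set.seed() on the R side fixes a training run.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

struct Params {
  mat W1, U1, b1, g1, be1, rm1, rv1;
  mat W2, U2, b2, g2, be2, rm2, rv2;
  mat Wa, va;
  mat Wd, bd, Wo, bo;
  bool attention;
};

static mat get_mat(const Rcpp::List& l, const char* nm) {
  return Rcpp::as<mat>(l[nm]);
}

static Params unpack(const Rcpp::List& l, bool attention) {
  Params p;
  p.W1 = get_mat(l, "W1"); p.U1 = get_mat(l, "U1"); p.b1 = get_mat(l, "b1");
  p.g1 = get_mat(l, "g1"); p.be1 = get_mat(l, "be1");
  p.rm1 = get_mat(l, "rm1"); p.rv1 = get_mat(l, "rv1");
  p.W2 = get_mat(l, "W2"); p.U2 = get_mat(l, "U2"); p.b2 = get_mat(l, "b2");
  p.g2 = get_mat(l, "g2"); p.be2 = get_mat(l, "be2");
  p.rm2 = get_mat(l, "rm2"); p.rv2 = get_mat(l, "rv2");
  p.attention = attention;
  if (attention) { p.Wa = get_mat(l, "Wa"); p.va = get_mat(l, "va"); }
  p.Wd = get_mat(l, "Wd"); p.bd = get_mat(l, "bd");
  p.Wo = get_mat(l, "Wo"); p.bo = get_mat(l, "bo");
  return p;
}

static Rcpp::List pack(const Params& p) {
  Rcpp::List l = Rcpp::List::create(
      Rcpp::Named("W1") = p.W1, Rcpp::Named("U1") = p.U1, Rcpp::Named("b1") = p.b1,
      Rcpp::Named("g1") = p.g1, Rcpp::Named("be1") = p.be1,
      Rcpp::Named("rm1") = p.rm1, Rcpp::Named("rv1") = p.rv1,
      Rcpp::Named("W2") = p.W2, Rcpp::Named("U2") = p.U2, Rcpp::Named("b2") = p.b2,
      Rcpp::Named("g2") = p.g2, Rcpp::Named("be2") = p.be2,
      Rcpp::Named("rm2") = p.rm2, Rcpp::Named("rv2") = p.rv2,
      Rcpp::Named("Wd") = p.Wd, Rcpp::Named("bd") = p.bd,
      Rcpp::Named("Wo") = p.Wo, Rcpp::Named("bo") = p.bo);
  if (p.attention) { l["Wa"] = p.Wa; l["va"] = p.va; }
  return l;
}

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// ---------------------------------------------------------------- LSTM layer

// Per-timestep gate caches plus the time-flattened input (B*T x in, rows
// grouped by timestep) so the input projection and the weight-gradient
// accumulations run as single large GEMMs; only the recurrence stays
// sequential.
struct LstmCache { cube I, F, G, O, C, H; mat InFlat; };

static void lstm_forward(const mat& W, const mat& U, const mat& b,
                         const cube& In, LstmCache& cc) {
  const uword B = In.n_rows, T = In.n_slices, H = U.n_rows;
  cc.I.set_size(B, H, T); cc.F.set_size(B, H, T); cc.G.set_size(B, H, T);
  cc.O.set_size(B, H, T); cc.C.set_size(B, H, T); cc.H.set_size(B, H, T);
  cc.InFlat.set_size(B * T, In.n_cols);
  for (uword t = 0; t < T; ++t) {
    cc.InFlat.rows(t * B, (t + 1) * B - 1) = In.slice(t);
  }
  mat PF = cc.InFlat * W;            // all input projections at once
  PF.each_row() += b.row(0);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat A = PF.rows(t * B, (t + 1) * B - 1) + h * U;
    mat i = sigm(A.cols(0, H - 1));
    mat f = sigm(A.cols(H, 2 * H - 1));
    mat g = tanh(A.cols(2 * H, 3 * H - 1));
    mat o = sigm(A.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    cc.I.slice(t) = i; cc.F.slice(t) = f; cc.G.slice(t) = g;
    cc.O.slice(t) = o; cc.C.slice(t) = c; cc.H.slice(t) = h;
  }
}

static void lstm_backward(const mat& W, const mat& U, const LstmCache& cc,
                          const cube& dH, mat& dW, mat& dU, mat& db,
                          cube& dIn) {
  const uword B = dH.n_rows, T = dH.n_slices, H = U.n_rows;
  mat dAFlat(B * T, 4 * H), HprevFlat(B * T, H);
  mat dc_next(B, H, fill::zeros), dh_carry(B, H, fill::zeros);
  for (uword ti = T; ti-- > 0;) {
    const mat& i = cc.I.slice(ti); const mat& f = cc.F.slice(ti);
    const mat& g = cc.G.slice(ti); const mat& o = cc.O.slice(ti);
    const mat tc = tanh(cc.C.slice(ti));
    mat dh = dH.slice(ti) + dh_carry;
    mat do_ = dh % tc;
    mat dc = dc_next + dh % o % (1.0 - tc % tc);
    mat c_prev = (ti == 0) ? mat(B, H, fill::zeros) : cc.C.slice(ti - 1);
    mat di = dc % g, dg = dc % i, df = dc % c_prev;
    dc_next = dc % f;
    mat dA(B, 4 * H);
    dA.cols(0, H - 1)         = di % i % (1.0 - i);
    dA.cols(H, 2 * H - 1)     = df % f % (1.0 - f);
    dA.cols(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    dA.cols(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    dAFlat.rows(ti * B, (ti + 1) * B - 1) = dA;
    HprevFlat.rows(ti * B, (ti + 1) * B - 1) =
        (ti == 0) ? mat(B, H, fill::zeros) : cc.H.slice(ti - 1);
    dh_carry = dA * U.t();
  }
  dW = cc.InFlat.t() * dAFlat;
  dU = HprevFlat.t() * dAFlat;
  db = sum(dAFlat, 0);
  mat dInFlat = dAFlat * W.t();
  dIn.set_size(B, dInFlat.n_cols, T);
  for (uword t = 0; t < T; ++t) {
    dIn.slice(t) = dInFlat.rows(t * B, (t + 1) * B - 1);
  }
}

// ------------------------------------------------------- batch normalization

struct BnCache { cube xhat; rowvec invstd; };

// feature-axis normalization over all (example, timestep) pairs
static void bn_forward(const mat& gamma, const mat& beta, mat& rmean,
                       mat& rvar, const cube& X, bool training, cube& Y,
                       BnCache& cc) {
  const uword B = X.n_rows, H = X.n_cols, T = X.n_slices;
  const double N = double(B) * double(T);
  rowvec mu(H), var(H);
  if (training) {
    mu.zeros();
    for (uword t = 0; t < T; ++t) mu += sum(X.slice(t), 0);
    mu /= N;
    var.zeros();
    for (uword t = 0; t < T; ++t) {
      mat d = X.slice(t); d.each_row() -= mu;
      var += sum(d % d, 0);
    }
    var /= N;
    rmean.row(0) = (1.0 - BN_MOMENTUM) * rmean.row(0) + BN_MOMENTUM * mu;
    rvar.row(0)  = (1.0 - BN_MOMENTUM) * rvar.row(0) + BN_MOMENTUM * var;
  } else {
    mu = rmean.row(0);
    var = rvar.row(0);
  }
  cc.invstd = 1.0 / sqrt(var + BN_EPS);
  cc.xhat.set_size(B, H, T);
  Y.set_size(B, H, T);
  const rowvec g = gamma.row(0), be = beta.row(0);
  for (uword t = 0; t < T; ++t) {
    mat xh = X.slice(t); xh.each_row() -= mu; xh.each_row() %= cc.invstd;
    cc.xhat.slice(t) = xh;
    xh.each_row() %= g; xh.each_row() += be;
    Y.slice(t) = xh;
  }
}

static void bn_backward(const mat& gamma, const cube& dY, const BnCache& cc,
                        mat& dgamma, mat& dbeta, cube& dX) {
  const uword B = dY.n_rows, H = dY.n_cols, T = dY.n_slices;
  const double N = double(B) * double(T);
  rowvec sum_dxh(H, fill::zeros), sum_dxh_xh(H, fill::zeros);
  dgamma.zeros(1, H); dbeta.zeros(1, H);
  const rowvec g = gamma.row(0);
  for (uword t = 0; t < T; ++t) {
    dbeta.row(0) += sum(dY.slice(t), 0);
    dgamma.row(0) += sum(dY.slice(t) % cc.xhat.slice(t), 0);
    mat dxh = dY.slice(t); dxh.each_row() %= g;
    sum_dxh += sum(dxh, 0);
    sum_dxh_xh += sum(dxh % cc.xhat.slice(t), 0);
  }
  dX.set_size(B, H, T);
  const rowvec scale = cc.invstd / N;
  for (uword t = 0; t < T; ++t) {
    mat dxh = dY.slice(t); dxh.each_row() %= g;
    mat term = N * dxh;
    term.each_row() -= sum_dxh;
    mat xs = cc.xhat.slice(t); xs.each_row() %= sum_dxh_xh;
    term -= xs;
    term.each_row() %= scale;
    dX.slice(t) = term;
  }
}

// ------------------------------------------------------------------ dropout

static void dropout_mask(cube& mask, double rate) {
  const double keep = 1.0 - rate;
  for (uword k = 0; k < mask.n_elem; ++k) {
    mask(k) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
  }
}

// ---------------------------------------------------------------- attention

// CatFlat is [z_t ; z_T] flattened over time (B*T x 2H), UFlat its tanh
// projection, so the scoring runs as one GEMM; A holds the softmax weights.
struct AttnCache { mat CatFlat, UFlat, A; };

// score_t = va' tanh(Wa [z_t; z_T]); weights = softmax over t;
// context = sum_t a_t z_t; returns q = [context; z_T]
static mat attn_forward(const mat& Wa, const mat& va, const cube& Z,
                        AttnCache& cc) {
  const uword B = Z.n_rows, H = Z.n_cols, T = Z.n_slices;
  const mat hn = Z.slice(T - 1);
  cc.CatFlat.set_size(B * T, 2 * H);
  for (uword t = 0; t < T; ++t) {
    cc.CatFlat.submat(t * B, 0, (t + 1) * B - 1, H - 1) = Z.slice(t);
    cc.CatFlat.submat(t * B, H, (t + 1) * B - 1, 2 * H - 1) = hn;
  }
  cc.UFlat = tanh(cc.CatFlat * Wa.t());  // B*T x A
  vec sflat = cc.UFlat * va;
  mat S(B, T);
  for (uword t = 0; t < T; ++t) S.col(t) = sflat.subvec(t * B, (t + 1) * B - 1);
  S.each_col() -= max(S, 1);
  mat Aw = exp(S);
  Aw.each_col() /= sum(Aw, 1);
  cc.A = Aw;
  mat context(B, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat zs = Z.slice(t); zs.each_col() %= Aw.col(t);
    context += zs;
  }
  return join_rows(context, hn);
}

static void attn_backward(const mat& Wa, const mat& va, const cube& Z,
                          const AttnCache& cc, const mat& dq,
                          mat& dWa, mat& dva, cube& dZ) {
  const uword B = Z.n_rows, H = Z.n_cols, T = Z.n_slices;
  const mat dcontext = dq.cols(0, H - 1);
  mat dhn = dq.cols(H, 2 * H - 1);
  dZ.zeros(B, H, T);
  mat da(B, T);
  for (uword t = 0; t < T; ++t) {
    da.col(t) = sum(dcontext % Z.slice(t), 1);
    mat dzs = dcontext; dzs.each_col() %= cc.A.col(t);
    dZ.slice(t) += dzs;
  }
  vec rowdot = sum(cc.A % da, 1);
  mat dS = da; dS.each_col() -= rowdot; dS %= cc.A;
  vec dSflat(B * T);
  for (uword t = 0; t < T; ++t) dSflat.subvec(t * B, (t + 1) * B - 1) = dS.col(t);
  mat dPre = dSflat * va.t();            // B*T x A
  dPre %= (1.0 - cc.UFlat % cc.UFlat);
  dva = cc.UFlat.t() * dSflat;
  dWa = dPre.t() * cc.CatFlat;
  mat dCat = dPre * Wa;                  // B*T x 2H
  for (uword t = 0; t < T; ++t) {
    dZ.slice(t) += dCat.submat(t * B, 0, (t + 1) * B - 1, H - 1);
    dhn += dCat.submat(t * B, H, (t + 1) * B - 1, 2 * H - 1);
  }
  dZ.slice(T - 1) += dhn;
}

// ------------------------------------------------------------- forward pass

struct FwdCache {
  LstmCache l1, l2;
  BnCache bn1, bn2;
  cube Y1, D1, Y2, Z, mask1, mask2;
  AttnCache at;
  mat q, d1, P;
  bool dropped;
};

static mat softmax_rows(mat logits) {
  logits.each_col() -= max(logits, 1);
  mat P = exp(logits);
  P.each_col() /= sum(P, 1);
  return P;
}

static void forward(Params& p, const cube& X, bool training, double dropout,
                    FwdCache& cc) {
  lstm_forward(p.W1, p.U1, p.b1, X, cc.l1);
  bn_forward(p.g1, p.be1, p.rm1, p.rv1, cc.l1.H, training, cc.Y1, cc.bn1);
  cc.dropped = training && dropout > 0.0;
  if (cc.dropped) {
    cc.mask1.set_size(size(cc.Y1)); dropout_mask(cc.mask1, dropout);
    cc.D1 = cc.Y1 % cc.mask1;
  } else {
    cc.D1 = cc.Y1;
  }
  lstm_forward(p.W2, p.U2, p.b2, cc.D1, cc.l2);
  bn_forward(p.g2, p.be2, p.rm2, p.rv2, cc.l2.H, training, cc.Y2, cc.bn2);
  if (cc.dropped) {
    cc.mask2.set_size(size(cc.Y2)); dropout_mask(cc.mask2, dropout);
    cc.Z = cc.Y2 % cc.mask2;
  } else {
    cc.Z = cc.Y2;
  }
  if (p.attention) {
    cc.q = attn_forward(p.Wa, p.va, cc.Z, cc.at);
  } else {
    cc.q = cc.Z.slice(cc.Z.n_slices - 1);
  }
  cc.d1 = tanh(cc.q * p.Wd + repmat(p.bd, cc.q.n_rows, 1));
  cc.P = softmax_rows(cc.d1 * p.Wo + repmat(p.bo, cc.q.n_rows, 1));
}

static double ce_loss(const mat& P, const ivec& y) {
  double L = 0.0;
  for (uword b = 0; b < P.n_rows; ++b) {
    L -= std::log(std::max(P(b, uword(y(b))), 1e-12));
  }
  return L / double(P.n_rows);
}

static void backward(Params& p, const cube& X, const ivec& y,
                     const FwdCache& cc, Params& g) {
  const uword B = X.n_rows, K = cc.P.n_cols;
  // head
  mat dlogits = cc.P;
  for (uword b = 0; b < B; ++b) dlogits(b, uword(y(b))) -= 1.0;
  dlogits /= double(B);
  g.Wo = cc.d1.t() * dlogits;
  g.bo = sum(dlogits, 0);
  mat dd1 = dlogits * p.Wo.t();
  mat dpre = dd1 % (1.0 - cc.d1 % cc.d1);
  g.Wd = cc.q.t() * dpre;
  g.bd = sum(dpre, 0);
  mat dq = dpre * p.Wd.t();
  // attention / final-state pick
  cube dZ;
  if (p.attention) {
    attn_backward(p.Wa, p.va, cc.Z, cc.at, dq, g.Wa, g.va, dZ);
  } else {
    dZ.zeros(size(cc.Z));
    dZ.slice(dZ.n_slices - 1) = dq;
  }
  if (cc.dropped) dZ %= cc.mask2;
  cube dH2;
  bn_backward(p.g2, dZ, cc.bn2, g.g2, g.be2, dH2);
  cube dD1;
  lstm_backward(p.W2, p.U2, cc.l2, dH2, g.W2, g.U2, g.b2, dD1);
  if (cc.dropped) dD1 %= cc.mask1;
  cube dH1;
  bn_backward(p.g1, dD1, cc.bn1, g.g1, g.be1, dH1);
  cube dX;
  lstm_backward(p.W1, p.U1, cc.l1, dH1, g.W1, g.U1, g.b1, dX);
  (void)K;
}

// collect pointers to the trainable parameters (running stats excluded)
static std::vector<mat*> trainable(Params& p) {
  std::vector<mat*> v = {&p.W1, &p.U1, &p.b1, &p.g1, &p.be1,
                         &p.W2, &p.U2, &p.b2, &p.g2, &p.be2};
  if (p.attention) { v.push_back(&p.Wa); v.push_back(&p.va); }
  v.push_back(&p.Wd); v.push_back(&p.bd); v.push_back(&p.Wo); v.push_back(&p.bo);
  return v;
}

// ------------------------------------------------------------------ exports

// eval-mode class probabilities (dropout off, running BN statistics)
// [[Rcpp::export]]
arma::mat cpp_predict(Rcpp::List params, arma::cube X, bool attention) {
  Params p = unpack(params, attention);
  FwdCache cc;
  forward(p, X, false, 0.0, cc);
  return cc.P;
}

// loss (and optionally analytic gradients) at fixed parameters; training=TRUE
// uses minibatch BN statistics, which is the mode the gradients correspond to
// [[Rcpp::export]]
Rcpp::List cpp_loss_grads(Rcpp::List params, arma::cube X, arma::ivec y,
                          bool attention, bool training = true,
                          bool want_grads = true) {
  Params p = unpack(params, attention);
  FwdCache cc;
  forward(p, X, training, 0.0, cc);
  double L = ce_loss(cc.P, y);
  if (!want_grads) return Rcpp::List::create(Rcpp::Named("loss") = L);
  Params g = p;  // shapes; values overwritten
  backward(p, X, y, cc, g);
  return Rcpp::List::create(Rcpp::Named("loss") = L,
                            Rcpp::Named("grads") = pack(g));
}

// full training loop: minibatch Adam with per-epoch train/validation loss
// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List params, arma::cube X, arma::ivec y,
                     arma::cube Xval, arma::ivec yval, bool attention,
                     int epochs, int batch_size, double lr, double dropout,
                     double beta1 = 0.9, double beta2 = 0.999,
                     double adam_eps = 1e-8) {
  Params p = unpack(params, attention);
  const uword n = X.n_rows;
  if (batch_size < 1) batch_size = 1;
  if (uword(batch_size) > n) batch_size = int(n);

  std::vector<mat*> tp = trainable(p);
  std::vector<mat> m(tp.size()), v(tp.size());
  for (size_t k = 0; k < tp.size(); ++k) {
    m[k].zeros(size(*tp[k]));
    v[k].zeros(size(*tp[k]));
  }

  vec train_loss(std::max(epochs, 0), fill::zeros);
  vec val_loss(std::max(epochs, 0), fill::zeros);
  double best_val = datum::inf;
  long step = 0;
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;

  auto eval_loss = [&](const cube& Xe, const ivec& ye) {
    FwdCache cc;
    Params pe = p;  // copy so eval never touches running stats
    forward(pe, Xe, false, 0.0, cc);
    return ce_loss(cc.P, ye);
  };

  if (epochs <= 0) {
    best_val = eval_loss(Xval, yval);
    return Rcpp::List::create(
        Rcpp::Named("params") = pack(p),
        Rcpp::Named("train_loss") = train_loss,
        Rcpp::Named("val_loss") = val_loss,
        Rcpp::Named("best_val") = best_val);
  }

  for (int e = 0; e < epochs; ++e) {
    // Fisher-Yates shuffle from R's RNG
    for (uword i = n - 1; i > 0; --i) {
      uword j = uword(unif_rand() * double(i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double epoch_loss = 0.0;
    int n_batches = 0;
    for (uword start = 0; start < n; start += uword(batch_size)) {
      uword stop = std::min(start + uword(batch_size), n) - 1;
      uword B = stop - start + 1;
      cube Xb(B, X.n_cols, X.n_slices);
      ivec yb(B);
      for (uword b = 0; b < B; ++b) {
        Xb.row(b) = X.row(idx[start + b]);
        yb(b) = y(idx[start + b]);
      }
      FwdCache cc;
      forward(p, Xb, true, dropout, cc);
      double L = ce_loss(cc.P, yb);
      if (!std::isfinite(L)) {
        Rcpp::stop("non-finite training loss at epoch %d", e + 1);
      }
      epoch_loss += L;
      ++n_batches;
      Params g = p;
      backward(p, Xb, yb, cc, g);
      std::vector<mat*> tg = trainable(g);
      ++step;
      const double bc1 = 1.0 - std::pow(beta1, double(step));
      const double bc2 = 1.0 - std::pow(beta2, double(step));
      for (size_t k = 0; k < tp.size(); ++k) {
        m[k] = beta1 * m[k] + (1.0 - beta1) * (*tg[k]);
        v[k] = beta2 * v[k] + (1.0 - beta2) * square(*tg[k]);
        *tp[k] -= lr * (m[k] / bc1) / (sqrt(v[k] / bc2) + adam_eps);
      }
    }
    train_loss(e) = epoch_loss / std::max(n_batches, 1);
    val_loss(e) = eval_loss(Xval, yval);
    if (val_loss(e) < best_val) best_val = val_loss(e);
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = pack(p),
      Rcpp::Named("train_loss") = train_loss,
      Rcpp::Named("val_loss") = val_loss,
      Rcpp::Named("best_val") = best_val);
}

// hidden-state sequence of a single LSTM layer (for cross-checks against the
// pure-R single-step cell)
// [[Rcpp::export]]
arma::cube cpp_lstm_sequence(arma::mat W, arma::mat U, arma::mat b,
                             arma::cube In) {
  LstmCache cc;
  lstm_forward(W, U, b, In, cc);
  return cc.H;
}
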