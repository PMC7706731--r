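// Hot numeric kernels of the sequence model. Orchestration, RNG (dropout
// masks) and the large dense-layer GEMMs stay in R; these kernels cover the
// loops R executes poorly: im2col, max pooling with argmax, the BiLSTM time
// step recursions (forward and BPTT), and the unpool / col2im scatters.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Xb: B x 4L one-hot (position-major); returns Z ((B*T) x 4K, t-major rows).
// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::mat& Xb, int K) {
  const int B = Xb.n_rows;
  const int L4 = Xb.n_cols;
  const int L = L4 / 4;
  const int T = L - K + 1;
  arma::mat Z(B * (size_t)T, 4 * (size_t)K);
  for (int t = 0; t < T; ++t) {
    Z.rows((size_t)t * B, (size_t)(t + 1) * B - 1) =
      Xb.cols(4 * (size_t)t, 4 * (size_t)t + 4 * K - 1);
  }
  return Z;
}

// Scatter dZ ((B*T) x 4K) back onto the input layout (B x 4L).
// [[Rcpp::export]]
arma::mat cpp_col2im(const arma::mat& dZ, int B, int L, int K) {
  const int T = L - K + 1;
  arma::mat dXb(B, 4 * (size_t)L, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    dXb.cols(4 * (size_t)t, 4 * (size_t)t + 4 * K - 1) +=
      dZ.rows((size_t)t * B, (size_t)(t + 1) * B - 1);
  }
  return dXb;
}

// Conv + bias + ReLU: A1 = relu(Z * Wc + bc). Returns both Z and A1.
// [[Rcpp::export]]
List cpp_conv_forward(const arma::mat& Xb, const arma::mat& Wc,
                      const arma::vec& bc) {
  const int K = Wc.n_rows / 4;
  arma::mat Z = cpp_im2col(Xb, K);
  arma::mat A1 = Z * Wc;
  for (arma::uword f = 0; f < A1.n_cols; ++f) {
    double* col = A1.colptr(f);
    const double b = bc(f);
    const arma::uword n = A1.n_rows;
    for (arma::uword i = 0; i < n; ++i) {
      const double v = col[i] + b;
      col[i] = v > 0 ? v : 0;
    }
  }
  return List::create(_["Z"] = Z, _["A1"] = A1);
}

// Non-overlapping max pooling over t-blocks. A1: (T*B) x F, rows t-major.
// Returns M ((P*B) x F) and 1-based argmax within each pool window.
// [[Rcpp::export]]
List cpp_pool_max(const arma::mat& A1, int B, int P, int pool) {
  const int Fn = A1.n_cols;
  arma::mat M(P * (size_t)B, Fn);
  arma::imat amax(P * (size_t)B, Fn);
  for (int p = 0; p < P; ++p) {
    const int t0 = p * pool;
    for (int f = 0; f < Fn; ++f) {
      for (int b = 0; b < B; ++b) {
        double best = A1((size_t)t0 * B + b, f);
        int arg = 1;
        for (int j = 1; j < pool; ++j) {
          const double v = A1((size_t)(t0 + j) * B + b, f);
          if (v > best) { best = v; arg = j + 1; }
        }
        M((size_t)p * B + b, f) = best;
        amax((size_t)p * B + b, f) = arg;
      }
    }
  }
  return List::create(_["M"] = M, _["amax"] = amax);
}

// Route pooled gradients back to conv positions (through argmax), then
// apply the conv ReLU mask. dM: (P*B) x F. Returns dA1 ((T*B) x F).
// [[Rcpp::export]]
arma::mat cpp_unpool(const arma::mat& dM, const arma::imat& amax,
                     const arma::mat& A1, int B, int P, int pool, int T) {
  const int Fn = dM.n_cols;
  arma::mat dA1(T * (size_t)B, Fn, arma::fill::zeros);
  for (int p = 0; p < P; ++p) {
    for (int f = 0; f < Fn; ++f) {
      for (int b = 0; b < B; ++b) {
        const size_t src = (size_t)p * B + b;
        const int t = p * pool + amax(src, f) - 1;
        const size_t dst = (size_t)t * B + b;
        if (A1(dst, f) > 0) dA1(dst, f) = dM(src, f);
      }
    }
  }
  return dA1;
}

static inline arma::mat sigm(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// ---- fused full-network kernels --------------------------------------------
// One C++ entry point per training batch / inference chunk keeps all
// intermediates (tens of MB per batch) on the C++ side; only parameters,
// inputs and gradients cross the R boundary.

struct LstmCache {
  arma::mat Hseq, I, F, G, O, Tc, Cprev, Xm, Hm;
};

static void lstm_fwd_run(const arma::mat& S, const arma::mat& Wx,
                         const arma::mat& Wh, const arma::vec& b,
                         int B, int P, bool fwd,
                         const arma::mat* mx, const arma::mat* mh,
                         bool want_cache, LstmCache& cc) {
  const int H = Wh.n_rows;
  arma::mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  cc.Hseq.set_size(P * (size_t)B, H);
  const size_t cr = want_cache ? P * (size_t)B : 1;
  cc.I.set_size(cr, H); cc.F.set_size(cr, H); cc.G.set_size(cr, H);
  cc.O.set_size(cr, H); cc.Tc.set_size(cr, H); cc.Cprev.set_size(cr, H);
  cc.Hm.set_size(cr, H);
  cc.Xm = S;
  if (mx) {
    for (int p = 0; p < P; ++p) {
      cc.Xm.rows((size_t)p * B, (size_t)(p + 1) * B - 1) %= *mx;
    }
  }
  arma::mat XWx = cc.Xm * Wx;
  for (arma::uword j = 0; j < XWx.n_cols; ++j) XWx.col(j) += b(j);
  for (int k = 0; k < P; ++k) {
    const int p = fwd ? k : (P - 1 - k);
    const size_t r0 = (size_t)p * B, r1 = (size_t)(p + 1) * B - 1;
    arma::mat hprev = h;
    if (mh) hprev %= *mh;
    arma::mat G = XWx.rows(r0, r1) + hprev * Wh;
    const int H2 = H;
    arma::mat gi = sigm(G.cols(0, H2 - 1));
    arma::mat gf = sigm(G.cols(H2, 2 * H2 - 1));
    arma::mat gg = arma::tanh(G.cols(2 * H2, 3 * H2 - 1));
    arma::mat go = sigm(G.cols(3 * H2, 4 * H2 - 1));
    if (want_cache) cc.Cprev.rows(r0, r1) = c;
    c = gf % c + gi % gg;
    arma::mat tc = arma::tanh(c);
    h = go % tc;
    cc.Hseq.rows(r0, r1) = h;
    if (want_cache) {
      cc.I.rows(r0, r1) = gi; cc.F.rows(r0, r1) = gf; cc.G.rows(r0, r1) = gg;
      cc.O.rows(r0, r1) = go; cc.Tc.rows(r0, r1) = tc;
      cc.Hm.rows(r0, r1) = hprev;
    }
  }
}

static void lstm_bwd_run(const LstmCache& cc, const arma::mat& dHseq,
                         const arma::mat& Wx, const arma::mat& Wh,
                         arma::mat& dS, int B, int P, bool fwd,
                         const arma::mat* mx, const arma::mat* mh,
                         arma::mat& dWx, arma::mat& dWh, arma::vec& db) {
  const int H = Wh.n_rows;
  arma::mat dh_next(B, H, arma::fill::zeros), dc_next(B, H, arma::fill::zeros);
  arma::mat dGall(P * (size_t)B, 4 * (size_t)H);
  for (int k = P - 1; k >= 0; --k) {
    const int p = fwd ? k : (P - 1 - k);
    const size_t r0 = (size_t)p * B, r1 = (size_t)(p + 1) * B - 1;
    arma::mat gi = cc.I.rows(r0, r1), gf = cc.F.rows(r0, r1),
              gg = cc.G.rows(r0, r1), go = cc.O.rows(r0, r1),
              tc = cc.Tc.rows(r0, r1);
    arma::mat dh = dHseq.rows(r0, r1) + dh_next;
    arma::mat dc = dc_next + dh % go % (1.0 - tc % tc);
    arma::mat dG(B, 4 * (size_t)H);
    dG.cols(0, H - 1) = (dc % gg) % gi % (1.0 - gi);
    dG.cols(H, 2 * H - 1) = (dc % cc.Cprev.rows(r0, r1)) % gf % (1.0 - gf);
    dG.cols(2 * H, 3 * H - 1) = (dc % gi) % (1.0 - gg % gg);
    dG.cols(3 * H, 4 * H - 1) = (dh % tc) % go % (1.0 - go);
    dGall.rows(r0, r1) = dG;
    dh_next = dG * Wh.t();
    if (mh) dh_next %= *mh;
    dc_next = dc % gf;
  }
  dWx = cc.Xm.t() * dGall;
  dWh = cc.Hm.t() * dGall;
  db = arma::sum(dGall, 0).t();
  arma::mat dxp = dGall * Wx.t();
  if (mx) {
    for (int p = 0; p < P; ++p) {
      dxp.rows((size_t)p * B, (size_t)(p + 1) * B - 1) %= *mx;
    }
  }
  dS += dxp;
}

static arma::mat get_mask(const List& masks, const char* nm) {
  if (!masks.containsElementNamed(nm)) return arma::mat();
  RObject o = masks[nm];
  if (o.isNULL()) return arma::mat();
  return as<arma::mat>(o);
}

// Full forward + backward for one minibatch. Returns loss and parameter
// gradients; optionally the input gradient (for attributions, dlogits_
// overrides the BCE gradient).
// [[Rcpp::export]]
List cpp_batch(const arma::mat& Xb, const arma::mat& Y, const List& params,
               const List& masks, int pool, int P, bool want_grads,
               bool want_dXb, int grad_class = 0) {
  const arma::mat Wc = params["Wc"];
  const arma::vec bc = params["bc"];
  const arma::mat Wp = params["Wp"];
  const arma::vec bp = params["bp"];
  const arma::mat Wx_f = params["Wx_f"], Wh_f = params["Wh_f"];
  const arma::vec b_f = params["b_f"];
  const arma::mat Wx_b = params["Wx_b"], Wh_b = params["Wh_b"];
  const arma::vec b_b = params["b_b"];
  const arma::mat Wd = params["Wd"];
  const arma::vec bd = params["bd"];
  const arma::mat Wo = params["Wo"];
  const arma::vec bo = params["bo"];
  const int B = Xb.n_rows;
  const int K = Wc.n_rows / 4;
  const int L = Xb.n_cols / 4;
  const int T = L - K + 1;
  const int H = Wh_f.n_rows;
  const int Fn = Wc.n_cols;

  arma::mat m_pool = get_mask(masks, "pool"), m_rec = get_mask(masks, "rec"),
            m_dense = get_mask(masks, "dense"),
            mx_f = get_mask(masks, "mx_f"), mh_f = get_mask(masks, "mh_f"),
            mx_b = get_mask(masks, "mx_b"), mh_b = get_mask(masks, "mh_b");
  const arma::mat* pmx_f = mx_f.n_elem ? &mx_f : nullptr;
  const arma::mat* pmh_f = mh_f.n_elem ? &mh_f : nullptr;
  const arma::mat* pmx_b = mx_b.n_elem ? &mx_b : nullptr;
  const arma::mat* pmh_b = mh_b.n_elem ? &mh_b : nullptr;

  // conv + bias + relu
  arma::mat Z = cpp_im2col(Xb, K);
  arma::mat A1 = Z * Wc;
  for (int f = 0; f < Fn; ++f) {
    double* col = A1.colptr(f);
    const double b = bc(f);
    for (size_t i = 0; i < A1.n_rows; ++i) {
      const double v = col[i] + b;
      col[i] = v > 0 ? v : 0;
    }
  }
  // pool
  arma::mat M(P * (size_t)B, Fn);
  arma::imat amax(P * (size_t)B, Fn);
  for (int p = 0; p < P; ++p) {
    const int t0 = p * pool;
    for (int f = 0; f < Fn; ++f) {
      for (int b2 = 0; b2 < B; ++b2) {
        double best = A1((size_t)t0 * B + b2, f);
        int arg = 1;
        for (int j = 1; j < pool; ++j) {
          const double v = A1((size_t)(t0 + j) * B + b2, f);
          if (v > best) { best = v; arg = j + 1; }
        }
        M((size_t)p * B + b2, f) = best;
        amax((size_t)p * B + b2, f) = arg;
      }
    }
  }
  arma::mat Md = M;
  if (m_pool.n_elem) Md %= m_pool;
  arma::mat S = Md * Wp;
  for (arma::uword j = 0; j < S.n_cols; ++j) S.col(j) += bp(j);
  // BiLSTM
  LstmCache cf_, cb_;
  lstm_fwd_run(S, Wx_f, Wh_f, b_f, B, P, true, pmx_f, pmh_f, want_grads, cf_);
  lstm_fwd_run(S, Wx_b, Wh_b, b_b, B, P, false, pmx_b, pmh_b, want_grads, cb_);
  arma::mat Hcat = arma::join_rows(cf_.Hseq, cb_.Hseq);
  arma::mat Hd = Hcat;
  if (m_rec.n_elem) Hd %= m_rec;
  // flatten: Fl(b, (p-1)*2H + j) = Hd((p-1)*B + b, j)
  arma::mat Fl(B, (size_t)P * 2 * H);
  for (int p = 0; p < P; ++p) {
    for (int j = 0; j < 2 * H; ++j) {
      const double* src = Hd.colptr(j) + (size_t)p * B;
      double* dst = Fl.colptr((size_t)p * 2 * H + j);
      std::copy(src, src + B, dst);
    }
  }
  arma::mat Dh_pre = Fl * Wd;
  for (arma::uword j = 0; j < Dh_pre.n_cols; ++j) Dh_pre.col(j) += bd(j);
  arma::mat Dh = Dh_pre;
  Dh.for_each([](double& v) { if (v < 0) v = 0; });
  arma::mat Dhd = Dh;
  if (m_dense.n_elem) Dhd %= m_dense;
  arma::mat logits = Dhd * Wo;
  for (arma::uword j = 0; j < logits.n_cols; ++j) logits.col(j) += bo(j);
  arma::mat out = sigm(logits);
  // loss
  arma::mat pcl = arma::clamp(out, 1e-7, 1 - 1e-7);
  double loss = -arma::accu(Y % arma::log(pcl) +
                            (1.0 - Y) % arma::log(1.0 - pcl)) / Y.n_elem;
  if (!want_grads) {
    return List::create(_["loss"] = loss, _["out"] = out,
                        _["embedding"] = Dh);
  }
  // backward
  arma::mat dlogits;
  if (grad_class > 0) {
    // gradient of out[, grad_class] w.r.t. logits (for input attributions)
    dlogits.zeros(B, out.n_cols);
    dlogits.col(grad_class - 1) =
      out.col(grad_class - 1) % (1.0 - out.col(grad_class - 1));
  } else {
    dlogits = (out - Y) / (double)Y.n_elem;
  }
  arma::mat gWo = Dhd.t() * dlogits;
  arma::vec gbo = arma::sum(dlogits, 0).t();
  arma::mat dDhd = dlogits * Wo.t();
  if (m_dense.n_elem) dDhd %= m_dense;
  arma::mat dDh_pre = dDhd % (Dh_pre > 0);
  arma::mat gWd = Fl.t() * dDh_pre;
  arma::vec gbd = arma::sum(dDh_pre, 0).t();
  arma::mat dFl = dDh_pre * Wd.t();
  arma::mat dHd(P * (size_t)B, 2 * (size_t)H);
  for (int p = 0; p < P; ++p) {
    for (int j = 0; j < 2 * H; ++j) {
      const double* src = dFl.colptr((size_t)p * 2 * H + j);
      double* dst = dHd.colptr(j) + (size_t)p * B;
      std::copy(src, src + B, dst);
    }
  }
  if (m_rec.n_elem) dHd %= m_rec;
  arma::mat dS(P * (size_t)B, S.n_cols, arma::fill::zeros);
  arma::mat gWx_f, gWh_f, gWx_b, gWh_b;
  arma::vec gb_f, gb_b;
  lstm_bwd_run(cf_, dHd.cols(0, H - 1), Wx_f, Wh_f, dS, B, P, true,
               pmx_f, pmh_f, gWx_f, gWh_f, gb_f);
  lstm_bwd_run(cb_, dHd.cols(H, 2 * H - 1), Wx_b, Wh_b, dS, B, P, false,
               pmx_b, pmh_b, gWx_b, gWh_b, gb_b);
  arma::mat gWp = Md.t() * dS;
  arma::vec gbp = arma::sum(dS, 0).t();
  arma::mat dMd = dS * Wp.t();
  if (m_pool.n_elem) dMd %= m_pool;
  // unpool + relu mask
  arma::mat dA1(T * (size_t)B, Fn, arma::fill::zeros);
  for (int p = 0; p < P; ++p) {
    for (int f = 0; f < Fn; ++f) {
      for (int b2 = 0; b2 < B; ++b2) {
        const size_t src = (size_t)p * B + b2;
        const int t = p * pool + amax(src, f) - 1;
        const size_t dst = (size_t)t * B + b2;
        if (A1(dst, f) > 0) dA1(dst, f) = dMd(src, f);
      }
    }
  }
  arma::mat gWc = Z.t() * dA1;
  arma::vec gbc = arma::sum(dA1, 0).t();
  List grads = List::create(
    _["Wc"] = gWc, _["bc"] = gbc, _["Wp"] = gWp, _["bp"] = gbp,
    _["Wx_f"] = gWx_f, _["Wh_f"] = gWh_f, _["b_f"] = gb_f,
    _["Wx_b"] = gWx_b, _["Wh_b"] = gWh_b, _["b_b"] = gb_b,
    _["Wd"] = gWd, _["bd"] = gbd, _["Wo"] = gWo, _["bo"] = gbo
  );
  if (want_dXb) {
    arma::mat dZ = dA1 * Wc.t();
    arma::mat dXb = cpp_col2im(dZ, B, L, K);
    return List::create(_["loss"] = loss, _["out"] = out, _["grads"] = grads,
                        _["dXb"] = dXb);
  }
  return List::create(_["loss"] = loss, _["out"] = out, _["grads"] = grads);
}

// LSTM over P steps. S: (P*B) x D with t-major row blocks; `fwd` selects
// the reading direction. Optional variational dropout masks mx (B x D) and
// mh (B x H) are applied to the step input and the previous hidden state.
// Caches are returned as (P*B) x H matrices indexed like S.
// [[Rcpp::export]]
List cpp_lstm_forward(const arma::mat& S, const arma::mat& Wx,
                      const arma::mat& Wh, const arma::vec& b,
                      int B, int P, bool fwd,
                      Nullable<NumericMatrix> mx_ = R_NilValue,
                      Nullable<NumericMatrix> mh_ = R_NilValue,
                      bool want_cache = true) {
  const int H = Wh.n_rows;
  const bool use_mx = mx_.isNotNull();
  const bool use_mh = mh_.isNotNull();
  arma::mat mx, mh;
  if (use_mx) mx = as<arma::mat>(mx_);
  if (use_mh) mh = as<arma::mat>(mh_);
  arma::mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  arma::mat Hseq(P * (size_t)B, H);
  const size_t cache_rows = want_cache ? P * (size_t)B : 1;
  arma::mat Ic(cache_rows, H), Fc(cache_rows, H), Gc(cache_rows, H),
            Oc(cache_rows, H), Tc(cache_rows, H), Cprev(cache_rows, H),
            Xm(P * (size_t)B, S.n_cols), Hm(cache_rows, H);
  // the input projection has no time dependency: one large GEMM up front
  Xm = S;
  if (use_mx) {
    for (int p = 0; p < P; ++p) {
      Xm.rows((size_t)p * B, (size_t)(p + 1) * B - 1) %= mx;
    }
  }
  arma::mat XWx = Xm * Wx;
  for (arma::uword j = 0; j < XWx.n_cols; ++j) XWx.col(j) += b(j);
  for (int k = 0; k < P; ++k) {
    const int p = fwd ? k : (P - 1 - k);
    const size_t r0 = (size_t)p * B, r1 = (size_t)(p + 1) * B - 1;
    arma::mat hprev = h;
    if (use_mh) hprev %= mh;
    arma::mat G = XWx.rows(r0, r1) + hprev * Wh;
    arma::mat gi = sigm(G.cols(0, H - 1));
    arma::mat gf = sigm(G.cols(H, 2 * H - 1));
    arma::mat gg = arma::tanh(G.cols(2 * H, 3 * H - 1));
    arma::mat go = sigm(G.cols(3 * H, 4 * H - 1));
    if (want_cache) Cprev.rows(r0, r1) = c;
    c = gf % c + gi % gg;
    arma::mat tc = arma::tanh(c);
    h = go % tc;
    Hseq.rows(r0, r1) = h;
    if (want_cache) {
      Ic.rows(r0, r1) = gi; Fc.rows(r0, r1) = gf; Gc.rows(r0, r1) = gg;
      Oc.rows(r0, r1) = go; Tc.rows(r0, r1) = tc;
      Hm.rows(r0, r1) = hprev;
    }
  }
  return List::create(_["Hseq"] = Hseq, _["I"] = Ic, _["F"] = Fc,
                      _["G"] = Gc, _["O"] = Oc, _["Tc"] = Tc,
                      _["Cprev"] = Cprev, _["Xm"] = Xm, _["Hm"] = Hm);
}

// Backward pass (BPTT) matching cpp_lstm_forward. dHseq: (P*B) x H.
// Adds input gradients into dS (modified copy returned).
// [[Rcpp::export]]
List cpp_lstm_backward(const List& cache, const arma::mat& dHseq,
                       const arma::mat& Wx, const arma::mat& Wh,
                       arma::mat dS, int B, int P, bool fwd,
                       Nullable<NumericMatrix> mx_ = R_NilValue,
                       Nullable<NumericMatrix> mh_ = R_NilValue) {
  const int H = Wh.n_rows;
  const bool use_mx = mx_.isNotNull();
  const bool use_mh = mh_.isNotNull();
  arma::mat mx, mh;
  if (use_mx) mx = as<arma::mat>(mx_);
  if (use_mh) mh = as<arma::mat>(mh_);
  const arma::mat& Ic = cache["I"];
  const arma::mat& Fc = cache["F"];
  const arma::mat& Gc = cache["G"];
  const arma::mat& Oc = cache["O"];
  const arma::mat& Tc = cache["Tc"];
  const arma::mat& Cprev = cache["Cprev"];
  const arma::mat& Xm = cache["Xm"];
  const arma::mat& Hm = cache["Hm"];
  arma::mat dh_next(B, H, arma::fill::zeros), dc_next(B, H, arma::fill::zeros);
  arma::mat dGall(P * (size_t)B, 4 * (size_t)H);
  for (int k = P - 1; k >= 0; --k) {
    const int p = fwd ? k : (P - 1 - k);
    const size_t r0 = (size_t)p * B, r1 = (size_t)(p + 1) * B - 1;
    arma::mat gi = Ic.rows(r0, r1), gf = Fc.rows(r0, r1),
              gg = Gc.rows(r0, r1), go = Oc.rows(r0, r1),
              tc = Tc.rows(r0, r1);
    arma::mat dh = dHseq.rows(r0, r1) + dh_next;
    arma::mat dc = dc_next + dh % go % (1.0 - tc % tc);
    arma::mat dG(B, 4 * (size_t)H);
    dG.cols(0, H - 1) = (dc % gg) % gi % (1.0 - gi);
    dG.cols(H, 2 * H - 1) = (dc % Cprev.rows(r0, r1)) % gf % (1.0 - gf);
    dG.cols(2 * H, 3 * H - 1) = (dc % gi) % (1.0 - gg % gg);
    dG.cols(3 * H, 4 * H - 1) = (dh % tc) % go % (1.0 - go);
    dGall.rows(r0, r1) = dG;
    dh_next = dG * Wh.t();
    if (use_mh) dh_next %= mh;
    dc_next = dc % gf;
  }
  // weight/bias/input gradients batch over all time steps in single GEMMs
  arma::mat dWx = Xm.t() * dGall;
  arma::mat dWh = Hm.t() * dGall;
  arma::vec db = arma::sum(dGall, 0).t();
  arma::mat dxp = dGall * Wx.t();
  if (use_mx) {
    for (int p = 0; p < P; ++p) {
      dxp.rows((size_t)p * B, (size_t)(p + 1) * B - 1) %= mx;
    }
  }
  dS += dxp;
  return List::create(_["dWx"] = dWx, _["dWh"] = dWh, _["db"] = db,
                      _["dS"] = dS);
}
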