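// Fused forward/backward/update pass of the ISNet-1D training engine.
//
// Mirrors the reference R implementation layer for layer (same channels-first
// layout, same parameter names); the R path remains the definition used by
// the saliency code and the gradient-oracle tests, and a dedicated test
// asserts agreement between the two paths. The computation is templated on
// the element type: the diagnostic entry point and the prediction path run
// in double precision (parameters are aliased without copying), while the
// training step can run its forward/backward arithmetic in single precision
// for throughput -- parameters, optimiser state and the Adam update always
// stay in double precision, so freezing remains bit-exact.

#include <RcppArmadillo.h>
#include <vector>
#include <string>
#include <type_traits>
#include "conv1d_impl.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

template <typename eT>
static void relu_inplace(Mat<eT>& A) {
  eT* p = A.memptr();
  const uword n = A.n_elem;
  for (uword i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
}

// gradient mask from the post-activation values (y > 0 iff pre > 0)
template <typename eT>
static void relu_bwd_inplace(Mat<eT>& dA, const Mat<eT>& Y) {
  eT* d = dA.memptr();
  const eT* y = Y.memptr();
  const uword n = dA.n_elem;
  for (uword i = 0; i < n; ++i) if (y[i] <= 0) d[i] = 0;
}

template <typename eT>
static void pool2_fwd(const Mat<eT>& A, int L, int N, Mat<eT>& Y, umat& M) {
  const int C = A.n_rows, Lout = L / 2;
  Y.set_size(C, (uword)Lout * N);
  M.set_size(C, (uword)Lout * N);
  for (int n = 0; n < N; ++n) {
    for (int t = 0; t < Lout; ++t) {
      const eT* a1 = A.colptr((uword)n * L + 2 * t);
      const eT* a2 = A.colptr((uword)n * L + 2 * t + 1);
      eT* y = Y.colptr((uword)n * Lout + t);
      uword* m = M.colptr((uword)n * Lout + t);
      for (int c = 0; c < C; ++c) {
        if (a1[c] >= a2[c]) { y[c] = a1[c]; m[c] = 1; }
        else { y[c] = a2[c]; m[c] = 0; }
      }
    }
  }
}

template <typename eT>
static void pool2_bwd(const Mat<eT>& dY, const umat& M, int L, int N,
                      Mat<eT>& dA) {
  const int C = dY.n_rows, Lout = L / 2;
  dA.zeros(C, (uword)L * N);
  for (int n = 0; n < N; ++n) {
    for (int t = 0; t < Lout; ++t) {
      const eT* dy = dY.colptr((uword)n * Lout + t);
      const uword* m = M.colptr((uword)n * Lout + t);
      eT* d1 = dA.colptr((uword)n * L + 2 * t);
      eT* d2 = dA.colptr((uword)n * L + 2 * t + 1);
      for (int c = 0; c < C; ++c) {
        if (m[c]) d1[c] = dy[c]; else d2[c] = dy[c];
      }
    }
  }
}

// size-3, stride-1, same-padded max pool; ties resolved toward the earlier
// position (matching the R reference)
template <typename eT>
static void pool3_fwd(const Mat<eT>& A, int L, int N, Mat<eT>& Y, imat& M) {
  const int C = A.n_rows;
  Y.set_size(C, A.n_cols);
  M.set_size(C, A.n_cols);
  for (int n = 0; n < N; ++n) {
    for (int t = 0; t < L; ++t) {
      eT* y = Y.colptr((uword)n * L + t);
      sword* m = M.colptr((uword)n * L + t);
      const int dlo = (t == 0) ? 0 : -1;
      const int dhi = (t == L - 1) ? 0 : 1;
      for (int c = 0; c < C; ++c) {
        eT best = -Datum<eT>::inf;
        sword arg = 0;
        for (int d = dlo; d <= dhi; ++d) {
          const eT v = A.colptr((uword)n * L + t + d)[c];
          if (v > best) { best = v; arg = (sword)d; }
        }
        y[c] = best; m[c] = arg;
      }
    }
  }
}

template <typename eT>
static void pool3_bwd(const Mat<eT>& dY, const imat& M, int L, int N,
                      Mat<eT>& dA) {
  const int C = dY.n_rows;
  dA.zeros(C, dY.n_cols);
  for (int n = 0; n < N; ++n) {
    for (int t = 0; t < L; ++t) {
      const eT* dy = dY.colptr((uword)n * L + t);
      const sword* m = M.colptr((uword)n * L + t);
      for (int c = 0; c < C; ++c) {
        dA.colptr((uword)n * L + t + m[c])[c] += dy[c];
      }
    }
  }
}

// per-sample spatial mean (squeeze); s is C x N
template <typename eT>
static void gap_fwd(const Mat<eT>& A, int L, int N, Mat<eT>& s) {
  s.zeros(A.n_rows, N);
  for (int n = 0; n < N; ++n) {
    s.col(n) = sum(A.cols((uword)n * L, (uword)(n + 1) * L - 1), 1) / L;
  }
}

template <typename eT>
static void scale_by_gate(const Mat<eT>& A, const Mat<eT>& g, int L, int N,
                          Mat<eT>& Y) {
  const int C = A.n_rows;
  Y.set_size(C, A.n_cols);
  for (int n = 0; n < N; ++n) {
    const eT* gv = g.colptr(n);
    for (int t = 0; t < L; ++t) {
      const eT* a = A.colptr((uword)n * L + t);
      eT* y = Y.colptr((uword)n * L + t);
      for (int c = 0; c < C; ++c) y[c] = a[c] * gv[c];
    }
  }
}

struct StepCfg {
  int L0, L1, L2, sf, k1, kp, cc, cr, pf, fc;
};

static Rcpp::NumericVector as_rvec(const vec& x) {
  return Rcpp::NumericVector(x.begin(), x.end());
}

static StepCfg read_cfg(const List& cfg) {
  StepCfg c;
  c.L0 = cfg["input_length"]; c.L1 = cfg["L1"]; c.L2 = cfg["L2"];
  c.sf = cfg["stem_filters"]; c.k1 = cfg["stem_kernel"];
  c.kp = cfg["post_kernel"]; c.cc = cfg["concat_channels"];
  c.pf = cfg["post_filters"]; c.fc = cfg["fc_units"];
  const int red = cfg["se_reduction"];
  c.cr = c.cc / red;
  return c;
}

// order must match the R parameter list
static const char* PAR_NAMES[] = {
  "conv1_W", "conv1_b", "bn_gamma", "bn_beta",
  "i1_W", "i1_b", "i2a_W", "i2a_b", "i2b_W", "i2b_b",
  "i3a_W", "i3a_b", "i3b_W", "i3b_b", "i4_W", "i4_b",
  "se1_W", "se1_b", "se2_W", "se2_b",
  "conv2_W", "conv2_b", "fc1_W", "fc1_b", "out_W", "out_b"};
static const int N_PAR = 26;

static int par_index(const std::string& nm) {
  for (int i = 0; i < N_PAR; ++i) if (nm == PAR_NAMES[i]) return i;
  Rcpp::stop("unknown parameter name");
}

// parameter matrices in the working precision; double aliases R memory,
// float makes one cast per step
template <typename eT>
struct Params {
  Mat<eT> conv1_W, i1_W, i2a_W, i2b_W, i3a_W, i3b_W, i4_W,
          se1_W, se2_W, conv2_W, fc1_W, out_W;
  Col<eT> conv1_b, bn_gamma, bn_beta, i1_b, i2a_b, i2b_b, i3a_b, i3b_b,
          i4_b, se1_b, se2_b, conv2_b, fc1_b;
  eT out_b;
};

template <typename eT>
static Mat<eT> load_mat(const List& l, const char* nm) {
  Rcpp::NumericMatrix m = l[nm];
  if (std::is_same<eT, double>::value) {
    const mat v((double*)m.begin(), m.nrow(), m.ncol(), false, true);
    return conv_to<Mat<eT>>::from(v);
  }
  mat v((double*)m.begin(), m.nrow(), m.ncol(), false, true);
  return conv_to<Mat<eT>>::from(v);
}

template <typename eT>
static Col<eT> load_vec(const List& l, const char* nm) {
  Rcpp::NumericVector v = l[nm];
  const vec w((double*)v.begin(), v.size(), false, true);
  return conv_to<Col<eT>>::from(w);
}

template <typename eT>
static Params<eT> load_params(const List& par) {
  Params<eT> P;
  P.conv1_W = load_mat<eT>(par, "conv1_W"); P.conv1_b = load_vec<eT>(par, "conv1_b");
  P.bn_gamma = load_vec<eT>(par, "bn_gamma"); P.bn_beta = load_vec<eT>(par, "bn_beta");
  P.i1_W = load_mat<eT>(par, "i1_W"); P.i1_b = load_vec<eT>(par, "i1_b");
  P.i2a_W = load_mat<eT>(par, "i2a_W"); P.i2a_b = load_vec<eT>(par, "i2a_b");
  P.i2b_W = load_mat<eT>(par, "i2b_W"); P.i2b_b = load_vec<eT>(par, "i2b_b");
  P.i3a_W = load_mat<eT>(par, "i3a_W"); P.i3a_b = load_vec<eT>(par, "i3a_b");
  P.i3b_W = load_mat<eT>(par, "i3b_W"); P.i3b_b = load_vec<eT>(par, "i3b_b");
  P.i4_W = load_mat<eT>(par, "i4_W"); P.i4_b = load_vec<eT>(par, "i4_b");
  P.se1_W = load_mat<eT>(par, "se1_W"); P.se1_b = load_vec<eT>(par, "se1_b");
  P.se2_W = load_mat<eT>(par, "se2_W"); P.se2_b = load_vec<eT>(par, "se2_b");
  P.conv2_W = load_mat<eT>(par, "conv2_W"); P.conv2_b = load_vec<eT>(par, "conv2_b");
  P.fc1_W = load_mat<eT>(par, "fc1_W"); P.fc1_b = load_vec<eT>(par, "fc1_b");
  P.out_W = load_mat<eT>(par, "out_W");
  P.out_b = (eT)Rcpp::as<double>(par["out_b"]);
  return P;
}

template <typename eT>
struct Grads {
  std::vector<Mat<eT>> g;
  Grads() : g(N_PAR) {}
  Mat<eT>& operator[](int i) { return g[i]; }
};

// forward pass and, when grads != NULL, full backward pass
template <typename eT>
static void step_core(const Params<eT>& P, const List& buffers,
                      const Mat<eT>& x, const StepCfg& C, const Col<eT>& y,
                      bool bn_train, const Mat<eT>& dropout_mask,
                      vec& yhat_out, vec& run_mean_out, vec& run_var_out,
                      Grads<eT>* grads) {
  const int nb = x.n_rows;
  const Col<eT> run_mean = load_vec<eT>(buffers, "bn_mean");
  const Col<eT> run_var = load_vec<eT>(buffers, "bn_var");

  // ---- forward ----
  const Mat<eT> A0 = reshape(x.t(), 1, (uword)C.L0 * nb);
  Mat<eT> c1;
  conv1d_fwd_t<eT>(A0, P.conv1_W, P.conv1_b, C.L0, nb, C.k1, c1);

  Col<eT> mu, v;
  if (bn_train) {
    mu = mean(c1, 1);
    v = mean(square(c1), 1) - square(mu);
    run_mean_out = conv_to<vec>::from((eT)0.9 * run_mean + (eT)0.1 * mu);
    run_var_out = conv_to<vec>::from((eT)0.9 * run_var + (eT)0.1 * v);
  } else {
    mu = run_mean; v = run_var;
    run_mean_out = conv_to<vec>::from(run_mean);
    run_var_out = conv_to<vec>::from(run_var);
  }
  const Col<eT> ivar = 1.0 / sqrt(v + (eT)1e-5);
  Mat<eT> xhat = c1; xhat.each_col() -= mu; xhat.each_col() %= ivar;
  Mat<eT> r1 = xhat; r1.each_col() %= P.bn_gamma; r1.each_col() += P.bn_beta;
  relu_inplace(r1);

  Mat<eT> p1; umat m1;
  pool2_fwd(r1, C.L0, nb, p1, m1);

  Mat<eT> b1 = P.i1_W * p1; b1.each_col() += P.i1_b; relu_inplace(b1);
  Mat<eT> b2a = P.i2a_W * p1; b2a.each_col() += P.i2a_b; relu_inplace(b2a);
  Mat<eT> b2; conv1d_fwd_t<eT>(b2a, P.i2b_W, P.i2b_b, C.L1, nb, 3, b2);
  relu_inplace(b2);
  Mat<eT> b3a = P.i3a_W * p1; b3a.each_col() += P.i3a_b; relu_inplace(b3a);
  Mat<eT> b3; conv1d_fwd_t<eT>(b3a, P.i3b_W, P.i3b_b, C.L1, nb, 5, b3);
  relu_inplace(b3);
  Mat<eT> b4p; imat m4;
  pool3_fwd(p1, C.L1, nb, b4p, m4);
  Mat<eT> b4 = P.i4_W * b4p; b4.each_col() += P.i4_b; relu_inplace(b4);

  Mat<eT> ccat = join_cols(join_cols(b1, b2), join_cols(b3, b4));

  Mat<eT> s; gap_fwd(ccat, C.L1, nb, s);
  Mat<eT> h1 = P.se1_W * s; h1.each_col() += P.se1_b;
  Mat<eT> h1r = h1; relu_inplace(h1r);
  Mat<eT> z2 = P.se2_W * h1r; z2.each_col() += P.se2_b;
  const Mat<eT> gate = 1.0 / (1.0 + exp(-z2));
  Mat<eT> seY; scale_by_gate(ccat, gate, C.L1, nb, seY);

  Mat<eT> c2; conv1d_fwd_t<eT>(seY, P.conv2_W, P.conv2_b, C.L1, nb, C.kp, c2);
  Mat<eT> r2 = c2; relu_inplace(r2);
  Mat<eT> p2; umat m2;
  pool2_fwd(r2, C.L1, nb, p2, m2);

  const Mat<eT> Z = reshape(p2, (uword)C.pf * C.L2, nb);
  Mat<eT> h = P.fc1_W * Z; h.each_col() += P.fc1_b;
  Mat<eT> hr = h; relu_inplace(hr);
  const bool use_drop = dropout_mask.n_elem > 0;
  Mat<eT> hd = use_drop ? Mat<eT>(hr % dropout_mask) : hr;
  const Row<eT> yhat = P.out_W * hd + P.out_b;
  yhat_out = conv_to<vec>::from(yhat.t());
  if (grads == nullptr) return;

  // ---- backward (MSE gradient wrt predictions) ----
  Grads<eT>& g = *grads;
  const Row<eT> dyhat = (eT)2.0 * (yhat - y.t()) / nb;
  g[par_index("out_W")] = dyhat * hd.t();
  g[par_index("out_b")] = Mat<eT>(1, 1, fill::value(accu(dyhat)));
  Mat<eT> dhd = P.out_W.t() * dyhat;
  if (use_drop) dhd %= dropout_mask;
  relu_bwd_inplace(dhd, hr);
  g[par_index("fc1_W")] = dhd * Z.t();
  g[par_index("fc1_b")] = sum(dhd, 1);
  Mat<eT> dZ = P.fc1_W.t() * dhd;
  dZ.reshape((uword)C.pf, (uword)C.L2 * nb);

  Mat<eT> dr2; pool2_bwd(dZ, m2, C.L1, nb, dr2);
  relu_bwd_inplace(dr2, r2);
  Mat<eT> dseY, dc2W; Col<eT> dc2b;
  conv1d_bwd_t<eT>(seY, P.conv2_W, dr2, C.L1, nb, C.kp, dseY, dc2W, dc2b);
  g[par_index("conv2_W")] = dc2W; g[par_index("conv2_b")] = dc2b;

  // SE backward
  Mat<eT> dgate(C.cc, nb);
  for (int n = 0; n < nb; ++n) {
    dgate.col(n) = sum(dseY.cols((uword)n * C.L1, (uword)(n + 1) * C.L1 - 1) %
                       ccat.cols((uword)n * C.L1, (uword)(n + 1) * C.L1 - 1), 1);
  }
  Mat<eT> dz2 = dgate % gate % (1.0 - gate);
  g[par_index("se2_W")] = dz2 * h1r.t();
  g[par_index("se2_b")] = sum(dz2, 1);
  Mat<eT> dh1 = P.se2_W.t() * dz2;
  relu_bwd_inplace(dh1, h1r);
  g[par_index("se1_W")] = dh1 * s.t();
  g[par_index("se1_b")] = sum(dh1, 1);
  Mat<eT> ds = P.se1_W.t() * dh1 / C.L1;
  Mat<eT> dcc; scale_by_gate(dseY, gate, C.L1, nb, dcc);
  for (int n = 0; n < nb; ++n) {
    dcc.cols((uword)n * C.L1, (uword)(n + 1) * C.L1 - 1).each_col() += ds.col(n);
  }

  // split the concatenation back into branches
  const int f1 = b1.n_rows, f2 = b2.n_rows, f3 = b3.n_rows, f4 = b4.n_rows;
  Mat<eT> db1 = dcc.rows(0, f1 - 1);
  Mat<eT> db2 = dcc.rows(f1, f1 + f2 - 1);
  Mat<eT> db3 = dcc.rows(f1 + f2, f1 + f2 + f3 - 1);
  Mat<eT> db4 = dcc.rows(f1 + f2 + f3, f1 + f2 + f3 + f4 - 1);

  Mat<eT> dp1(C.sf, (uword)C.L1 * nb, fill::zeros);

  relu_bwd_inplace(db1, b1);
  g[par_index("i1_W")] = db1 * p1.t();
  g[par_index("i1_b")] = sum(db1, 1);
  dp1 += P.i1_W.t() * db1;

  relu_bwd_inplace(db2, b2);
  Mat<eT> db2a, di2bW; Col<eT> di2bb;
  conv1d_bwd_t<eT>(b2a, P.i2b_W, db2, C.L1, nb, 3, db2a, di2bW, di2bb);
  g[par_index("i2b_W")] = di2bW; g[par_index("i2b_b")] = di2bb;
  relu_bwd_inplace(db2a, b2a);
  g[par_index("i2a_W")] = db2a * p1.t();
  g[par_index("i2a_b")] = sum(db2a, 1);
  dp1 += P.i2a_W.t() * db2a;

  relu_bwd_inplace(db3, b3);
  Mat<eT> db3a, di3bW; Col<eT> di3bb;
  conv1d_bwd_t<eT>(b3a, P.i3b_W, db3, C.L1, nb, 5, db3a, di3bW, di3bb);
  g[par_index("i3b_W")] = di3bW; g[par_index("i3b_b")] = di3bb;
  relu_bwd_inplace(db3a, b3a);
  g[par_index("i3a_W")] = db3a * p1.t();
  g[par_index("i3a_b")] = sum(db3a, 1);
  dp1 += P.i3a_W.t() * db3a;

  relu_bwd_inplace(db4, b4);
  g[par_index("i4_W")] = db4 * b4p.t();
  g[par_index("i4_b")] = sum(db4, 1);
  Mat<eT> db4p = P.i4_W.t() * db4;
  Mat<eT> dp1_pool; pool3_bwd(db4p, m4, C.L1, nb, dp1_pool);
  dp1 += dp1_pool;

  Mat<eT> dr1; pool2_bwd(dp1, m1, C.L0, nb, dr1);
  relu_bwd_inplace(dr1, r1);

  // batch-norm backward
  g[par_index("bn_gamma")] = sum(dr1 % xhat, 1);
  g[par_index("bn_beta")] = sum(dr1, 1);
  Mat<eT> dxhat = dr1; dxhat.each_col() %= P.bn_gamma;
  Mat<eT> dc1;
  if (bn_train) {
    const eT M = (eT)c1.n_cols;
    Mat<eT> xc = c1; xc.each_col() -= mu;
    const Col<eT> dvar = sum(dxhat % xc, 1) % ((eT)-0.5 * pow(ivar, 3));
    const Col<eT> dmu = -sum(dxhat, 1) % ivar +
      dvar % mean((eT)-2.0 * xc, 1);
    dc1 = dxhat; dc1.each_col() %= ivar;
    xc.each_col() %= ((eT)2.0 * dvar / M);
    dc1 += xc;
    dc1.each_col() += dmu / M;
  } else {
    dc1 = dxhat; dc1.each_col() %= ivar;
  }

  Mat<eT> dA0, dc1W; Col<eT> dc1b;
  conv1d_bwd_t<eT>(A0, P.conv1_W, dc1, C.L0, nb, C.k1, dA0, dc1W, dc1b);
  g[par_index("conv1_W")] = dc1W; g[par_index("conv1_b")] = dc1b;
}

// diagnostic entry point: forward (+ optional gradient list) in double
// precision; used by the prediction engine and the R-vs-C++ agreement test
// [[Rcpp::export]]
Rcpp::List isnet_step_cpp(const Rcpp::List& par, const Rcpp::List& buffers,
                          const arma::mat& x, const Rcpp::List& cfg,
                          const arma::vec& y, bool bn_train,
                          const arma::mat& dropout_mask, bool want_grads) {
  const StepCfg C = read_cfg(cfg);
  const Params<double> P = load_params<double>(par);
  vec yhat, rm, rv;
  if (want_grads) {
    Grads<double> g;
    step_core<double>(P, buffers, x, C, y, bn_train, dropout_mask,
                      yhat, rm, rv, &g);
    List gl;
    for (int i = 0; i < N_PAR; ++i) {
      if (std::string(PAR_NAMES[i]) == "out_b") gl[PAR_NAMES[i]] = g[i](0, 0);
      else gl[PAR_NAMES[i]] = g[i];
    }
    return List::create(Named("yhat") = as_rvec(yhat),
                        Named("bn_mean") = as_rvec(rm),
                        Named("bn_var") = as_rvec(rv), Named("grads") = gl);
  }
  step_core<double>(P, buffers, x, C, y, bn_train, dropout_mask,
                    yhat, rm, rv, nullptr);
  return List::create(Named("yhat") = as_rvec(yhat),
                      Named("bn_mean") = as_rvec(rm),
                      Named("bn_var") = as_rvec(rv));
}

template <typename eT>
static List train_step(const List& par, const List& buffers, const mat& x,
                       const StepCfg& C, const vec& y, bool bn_train,
                       const mat& dropout_mask, const List& m, const List& v,
                       double lr, double lambda, int t_adam,
                       const Rcpp::NumericVector& lr_factors) {
  const Params<eT> P = load_params<eT>(par);
  vec yhat, rm, rv;
  Grads<eT> g;
  const Mat<eT> xe = conv_to<Mat<eT>>::from(x);
  const Col<eT> ye = conv_to<Col<eT>>::from(y);
  const Mat<eT> de = conv_to<Mat<eT>>::from(dropout_mask);
  step_core<eT>(P, buffers, xe, C, ye, bn_train, de, yhat, rm, rv, &g);

  // in-place Adam on the engine-owned parameter and moment lists: the R
  // engine deep-copies these lists on entry and at snapshots, so no other
  // reference can observe the mutation
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  const double bc1 = 1.0 - std::pow(b1, (double)t_adam);
  const double bc2 = 1.0 - std::pow(b2, (double)t_adam);
  const bool have_factors = lr_factors.size() > 0;
  for (int i = 0; i < N_PAR; ++i) {
    const std::string nm = PAR_NAMES[i];
    double f = 1.0;
    if (have_factors && lr_factors.containsElementNamed(nm.c_str())) {
      f = lr_factors[nm];
    }
    if (f == 0.0) continue;            // frozen: untouched, bit-identical
    const bool is_weight = nm.size() > 2 && nm.substr(nm.size() - 2) == "_W";
    Rcpp::NumericVector pv = par[nm.c_str()];
    Rcpp::NumericVector mv = m[nm.c_str()];
    Rcpp::NumericVector vv = v[nm.c_str()];
    double* p = pv.begin();
    double* mm = mv.begin();
    double* vvp = vv.begin();
    const eT* gp = g[i].memptr();
    const R_xlen_t n = pv.size();
    const double lf = lr * f;
    const double lam = is_weight ? lambda : 0.0;
    for (R_xlen_t j = 0; j < n; ++j) {
      const double gr = (double)gp[j] + lam * p[j];
      mm[j] = b1 * mm[j] + (1.0 - b1) * gr;
      vvp[j] = b2 * vvp[j] + (1.0 - b2) * gr * gr;
      p[j] -= lf * (mm[j] / bc1) / (std::sqrt(vvp[j] / bc2) + eps);
    }
  }
  return List::create(Named("yhat") = as_rvec(yhat),
                      Named("bn_mean") = as_rvec(rm),
                      Named("bn_var") = as_rvec(rv));
}

// fused training step: forward, backward, L2 penalty and in-place Adam
// update in one call; parameters with a zero learning-rate factor are never
// touched (bit-identical freezing)
// [[Rcpp::export]]
Rcpp::List isnet_train_step_cpp(const Rcpp::List& par, const Rcpp::List& buffers,
                                const arma::mat& x, const Rcpp::List& cfg,
                                const arma::vec& y, bool bn_train,
                                const arma::mat& dropout_mask,
                                const Rcpp::List& m, const Rcpp::List& v,
                                double lr, double lambda, int t_adam,
                                const Rcpp::NumericVector& lr_factors,
                                bool single_prec) {
  const StepCfg C = read_cfg(cfg);
  if (single_prec) {
    return train_step<float>(par, buffers, x, C, y, bn_train, dropout_mask,
                             m, v, lr, lambda, t_adam, lr_factors);
  }
  return train_step<double>(par, buffers, x, C, y, bn_train, dropout_mask,
                            m, v, lr, lambda, t_adam, lr_factors);
}
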