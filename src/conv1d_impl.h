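// Templated same-padded 1D convolution kernels shared by the double-precision
// exported wrappers and the single-precision training path.
#pragma once

#include <RcppArmadillo.h>

template <typename eT>
void conv1d_fwd_t(const arma::Mat<eT>& A, const arma::Mat<eT>& W,
                  const arma::Col<eT>& b, int L, int N, int k,
                  arma::Mat<eT>& Y) {
  using namespace arma;
  const int Cin = A.n_rows, Cout = W.n_rows;
  const int pad = (k - 1) / 2;
  Y.zeros(Cout, A.n_cols);
  for (int j = 0; j < k; ++j) {
    const int d = j - pad;
    const Mat<eT> Wj = W.cols(j * Cin, (j + 1) * Cin - 1);
    const int lo = std::max(0, -d), hi = std::min(L - 1, L - 1 - d);
    if (hi < lo) continue;
    const int len = hi - lo + 1;
    for (int n = 0; n < N; ++n) {
      const Mat<eT> Av(const_cast<eT*>(A.colptr((uword)n * L + lo + d)),
                       Cin, len, false, true);
      Mat<eT> Yv(Y.colptr((uword)n * L + lo), Cout, len, false, true);
      Yv += Wj * Av;
    }
  }
  Y.each_col() += b;
}

template <typename eT>
void conv1d_bwd_t(const arma::Mat<eT>& A, const arma::Mat<eT>& W,
                  const arma::Mat<eT>& dY, int L, int N, int k,
                  arma::Mat<eT>& dA, arma::Mat<eT>& dW, arma::Col<eT>& db) {
  using namespace arma;
  const int Cin = A.n_rows, Cout = W.n_rows;
  const int pad = (k - 1) / 2;
  dA.zeros(Cin, A.n_cols);
  dW.zeros(Cout, W.n_cols);
  db = sum(dY, 1);
  for (int j = 0; j < k; ++j) {
    const int d = j - pad;
    const Mat<eT> Wj = W.cols(j * Cin, (j + 1) * Cin - 1);
    const int lo = std::max(0, -d), hi = std::min(L - 1, L - 1 - d);
    if (hi < lo) continue;
    const int len = hi - lo + 1;
    Mat<eT> dWj(Cout, Cin, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      const Mat<eT> Av(const_cast<eT*>(A.colptr((uword)n * L + lo + d)),
                       Cin, len, false, true);
      const Mat<eT> dYv(const_cast<eT*>(dY.colptr((uword)n * L + lo)),
                        Cout, len, false, true);
      Mat<eT> dAv(dA.colptr((uword)n * L + lo + d), Cin, len, false, true);
      dWj += dYv * Av.t();
      dAv += Wj.t() * dYv;
    }
    dW.cols(j * Cin, (j + 1) * Cin - 1) = dWj;
  }
}
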