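// Exported double-precision wrappers around the shared convolution kernels
// (see conv1d_impl.h for the layout contract).

#include <RcppArmadillo.h>
#include "conv1d_impl.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat conv1d_fwd_cpp(const arma::mat& A, const arma::mat& W,
                         const arma::vec& b, int L, int N, int k) {
  mat Y;
  conv1d_fwd_t<double>(A, W, b, L, N, k, Y);
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const arma::mat& A, const arma::mat& W,
                          const arma::mat& dY, int L, int N, int k) {
  mat dA, dW;
  vec db;
  conv1d_bwd_t<double>(A, W, dY, L, N, k, dA, dW, db);
  return Rcpp::List::create(Rcpp::Named("dA") = dA,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
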