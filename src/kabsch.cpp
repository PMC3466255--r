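// Kabsch superposition RMSD: minimal RMSD over rigid rotation + translation,
// via SVD of the 3x3 cross-covariance with determinant sign correction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double kabsch_one(const arma::mat& A, const arma::mat& B) {
  const int n = A.n_rows;
  arma::rowvec ca = arma::mean(A, 0), cb = arma::mean(B, 0);
  arma::mat X = A.each_row() - ca;
  arma::mat Y = B.each_row() - cb;
  arma::mat C = X.t() * Y;
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, C)) return NA_REAL;
  double d = arma::det(V * U.t());
  arma::vec sign = {1.0, 1.0, d < 0 ? -1.0 : 1.0};
  double traced = arma::dot(s, sign);
  double e = (arma::accu(X % X) + arma::accu(Y % Y) - 2.0 * traced) / n;
  return std::sqrt(e > 0 ? e : 0);
}

// [[Rcpp::export]]
double kabsch_rmsd_cpp(const arma::mat& A, const arma::mat& B) {
  return kabsch_one(A, B);
}

// Pairwise RMSD over frames of a coordinate array (n_sel x 3 x F, flattened
// frame-major as produced by the DMD engine subsetting in R).
// [[Rcpp::export]]
NumericMatrix rmsd_matrix_cpp(const arma::cube& frames) {
  const int F = frames.n_slices;
  NumericMatrix M(F, F);
  for (int a = 0; a < F; ++a) {
    for (int b = a + 1; b < F; ++b) {
      double r = kabsch_one(frames.slice(a), frames.slice(b));
      M(a, b) = r; M(b, a) = r;
    }
    Rcpp::checkUserInterrupt();
  }
  return M;
}
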