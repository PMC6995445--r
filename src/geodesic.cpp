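// Pairwise affine-invariant geodesic distances between stacks of SPD
// matrices.  d_G(Q1, Q2) = sqrt(sum_i log^2 lambda_i) with lambda_i the
// eigenvalues of Q1^{-1/2} Q2 Q1^{-1/2}; each Q^{-1/2} is computed once per
// test matrix via a symmetric eigendecomposition, and the inner product is
// symmetrized before its eigendecomposition to suppress round-off
// asymmetry.  This is the hot path of an identification experiment (N^2
// pairs), hence C++.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat sym_inv_sqrt(const mat& q, double rel_tol, int which) {
  vec eval;
  mat evec;
  if (!eig_sym(eval, evec, symmatu(q))) {
    Rcpp::stop("eigendecomposition failed for matrix %d", which);
  }
  if (eval.min() <= rel_tol * eval.max()) {
    Rcpp::stop(
      "matrix %d is not positive definite (min eigenvalue %g); "
      "apply regularize_database() first", which, eval.min());
  }
  return evec * diagmat(1.0 / sqrt(eval)) * evec.t();
}

// [[Rcpp::export]]
arma::mat cpp_pairwise_geodesic(const arma::cube& test, const arma::cube& train,
                                double eig_tol) {
  const uword n_test = test.n_slices, n_train = train.n_slices;
  if (test.n_rows != train.n_rows) {
    Rcpp::stop("test and train matrices have different dimensions");
  }
  std::vector<mat> inv_sqrt(n_test);
  for (uword i = 0; i < n_test; ++i) {
    inv_sqrt[i] = sym_inv_sqrt(test.slice(i), eig_tol, (int)i + 1);
  }
  const uword n = test.n_rows;
  mat out(n_test, n_train);
  mat tmp(n, n), inner(n, n);
  vec lam(n);
  for (uword i = 0; i < n_test; ++i) {
    const mat& is = inv_sqrt[i];
    for (uword j = 0; j < n_train; ++j) {
      // PD check on the train side comes out in the eigenvalues below
      tmp = is * train.slice(j);
      inner = tmp * is;
      inner = 0.5 * (inner + inner.t());
      if (!eig_sym(lam, inner)) {
        Rcpp::stop("eigendecomposition failed for pair (%d, %d)",
                   (int)i + 1, (int)j + 1);
      }
      if (lam.min() <= eig_tol * lam.max()) {
        Rcpp::stop(
          "train matrix %d is not positive definite; "
          "apply regularize_database() first", (int)j + 1);
      }
      double s = 0.0;
      for (uword t = 0; t < n; ++t) {
        const double l = std::log(lam[t]);
        s += l * l;
      }
      out(i, j) = std::sqrt(s);
    }
  }
  return out;
}
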