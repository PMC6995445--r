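// Symmetric 1-NN identification accuracy on bootstrap resamples of a
// precomputed distance matrix.  Resampling never touches FC matrices: each
// resample is pure index arithmetic on D, so the cost of M x B resamples is
// independent of the ROI dimension.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// accuracy of one direction for one resample: rows of d are test
// participants (original indexing), columns train participants; idx holds
// the resampled original indices (0-based).  A test copy k is correct when
// the nearest train column (first minimum, i.e. lowest index on ties) is a
// copy of the same original participant.
static double dir_accuracy(const mat& d, const uvec& idx) {
  const uword n = idx.n_elem;
  uword correct = 0;
  for (uword k = 0; k < n; ++k) {
    const uword p = idx[k];
    double best = datum::inf;
    uword best_j = 0;
    for (uword t = 0; t < n; ++t) {
      const double v = d(p, idx[t]);
      if (v < best) {
        best = v;
        best_j = t;
      }
    }
    if (idx[best_j] == p) ++correct;
  }
  return (double)correct / (double)n;
}

// [[Rcpp::export]]
arma::vec cpp_resample_accuracy(const arma::mat& d12, const arma::mat& d21,
                                const arma::umat& idx) {
  // idx: M x N matrix of 0-based resampled participant indices
  const uword m = idx.n_rows;
  vec acc(m);
  for (uword r = 0; r < m; ++r) {
    const uvec row = idx.row(r).t();
    acc[r] = 0.5 * (dir_accuracy(d12, row) + dir_accuracy(d21, row));
  }
  return acc;
}
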