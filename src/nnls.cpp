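// Lawson-Hanson active-set non-negative least squares.
//
// min ||C a - d||_2  subject to  a >= 0
//
// Used in the inner loop of the unmixing engine, where thousands of small
// NNLS problems are solved per fit; a compiled kernel keeps the multi-start
// protocols fast and avoids fixed iteration caps on the augmented
// (sum-constrained) systems.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".nnls_solve")]]
arma::vec nnls_solve(const arma::mat& C, const arma::vec& d,
                     const double tol = -1.0) {
  const uword n = C.n_cols;
  vec a(n, fill::zeros);
  std::vector<bool> passive(n, false);
  vec w = C.t() * (d - C * a);
  const double eps = (tol > 0) ? tol
    : 10 * datum::eps * norm(C, 1) * static_cast<double>(C.n_rows);
  const uword max_outer = 10 * n + 100;

  for (uword outer = 0; outer < max_outer; ++outer) {
    // most violated KKT multiplier among the active (zero) set
    int j = -1;
    double wmax = eps;
    for (uword k = 0; k < n; ++k) {
      if (!passive[k] && w(k) > wmax) { wmax = w(k); j = static_cast<int>(k); }
    }
    if (j < 0) break;  // KKT satisfied
    passive[j] = true;

    for (uword inner = 0; inner < max_outer; ++inner) {
      uvec P(n);
      uword np = 0;
      for (uword k = 0; k < n; ++k) if (passive[k]) P(np++) = k;
      P.resize(np);
      vec z;
      if (!solve(z, C.cols(P), d)) {
        z = pinv(C.cols(P)) * d;  // rank-deficient passive set
      }
      if (z.min() > 0) {
        a.zeros();
        a.elem(P) = z;
        break;
      }
      // step back to the feasibility boundary and shrink the passive set
      double alpha = datum::inf;
      for (uword k = 0; k < np; ++k) {
        if (z(k) <= 0) {
          double cand = a(P(k)) / (a(P(k)) - z(k));
          if (cand < alpha) alpha = cand;
        }
      }
      for (uword k = 0; k < np; ++k)
        a(P(k)) += alpha * (z(k) - a(P(k)));
      for (uword k = 0; k < np; ++k) {
        if (a(P(k)) <= datum::eps * 100) { a(P(k)) = 0; passive[P(k)] = false; }
      }
    }
    w = C.t() * (d - C * a);
  }
  return a;
}
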