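#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Graphical lasso by block coordinate descent (Friedman-Hastie-Tibshirani):
// each column update solves a lasso on the current covariance estimate W.
// W_init / B_init allow warm starts along a regularization path.
// [[Rcpp::export(name = ".glasso_cd")]]
Rcpp::List glasso_cd(const arma::mat& S, double lambda,
                     arma::mat W, arma::mat B,
                     bool penalize_diagonal = false,
                     int maxit = 200, double tol = 1e-6,
                     int maxit_inner = 200, double tol_inner = 1e-8) {
  const uword p = S.n_rows;
  if (W.n_rows != p) {
    W = S;
    if (penalize_diagonal) W.diag() += lambda;
  }
  if (B.n_rows != p) B.zeros(p, p);

  // scale of the problem, for the relative convergence criterion
  double off = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j) off += std::abs(S(i, j));
  double thr = tol * (p > 1 ? off / (double)(p * (p - 1)) : 1.0);
  if (thr <= 0) thr = tol;

  int it = 0;
  bool converged = false;
  for (it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      // lasso for column j against W11 = W[-j,-j]
      for (int sweep = 0; sweep < maxit_inner; ++sweep) {
        double del = 0.0;
        for (uword k = 0; k < p; ++k) {
          if (k == j) continue;
          double r = S(k, j);
          for (uword l = 0; l < p; ++l) {
            if (l == j || l == k) continue;
            r -= W(k, l) * B(l, j);
          }
          double bnew = soft(r, lambda) / W(k, k);
          double d = std::abs(bnew - B(k, j));
          if (d > del) del = d;
          B(k, j) = bnew;
        }
        if (del < tol_inner) break;
      }
      // w12 = W11 * beta
      for (uword k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (uword l = 0; l < p; ++l) {
          if (l == j) continue;
          w += W(k, l) * B(l, j);
        }
        double d = std::abs(w - W(k, j));
        if (d > dmax) dmax = d;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    if (dmax < thr) { converged = true; break; }
  }

  // back out the precision matrix from (W, B)
  mat Omega(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    double denom = W(j, j);
    for (uword k = 0; k < p; ++k) {
      if (k == j) continue;
      denom -= W(k, j) * B(k, j);
    }
    double ojj = 1.0 / denom;
    Omega(j, j) = ojj;
    for (uword k = 0; k < p; ++k) {
      if (k == j) continue;
      Omega(k, j) = -B(k, j) * ojj;
    }
  }
  Omega = 0.5 * (Omega + Omega.t());

  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("Omega") = Omega,
                            Rcpp::Named("B") = B,
                            Rcpp::Named("iterations") = it + 1,
                            Rcpp::Named("converged") = converged);
}
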