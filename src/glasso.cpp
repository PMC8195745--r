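#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Graphical lasso by block coordinate descent (Friedman-style): each column of
// the working covariance W is updated by solving a lasso problem with
// coordinate descent. Off-diagonal penalties are given as a full matrix so a
// support-constrained refit (zero penalty on a fixed support, large penalty
// elsewhere) reuses the same solver. Diagonal entries are never penalised.
//
// Warm starts: W and B (per-column lasso coefficients) are taken as starting
// values and returned, so a penalty path can be solved efficiently.

static inline double soft_threshold(double x, double lam) {
  if (x > lam) return x - lam;
  if (x < -lam) return x + lam;
  return 0.0;
}

// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, const arma::mat& Lambda,
                      arma::mat W, arma::mat B,
                      double tol = 1e-4, int max_iter = 200,
                      double cd_tol = 1e-7, int cd_max_iter = 200) {
  const uword p = S.n_rows;
  if (S.n_cols != p || Lambda.n_rows != p || Lambda.n_cols != p)
    Rcpp::stop("S and Lambda must be square matrices of equal dimension");
  if (W.n_rows != p || B.n_rows != p)
    Rcpp::stop("warm-start matrices have wrong dimension");

  // diagonal is unpenalised: W_jj = S_jj at the optimum
  W.diag() = S.diag();

  // convergence threshold scaled by the average absolute off-diagonal of S
  double off_mean = 0.0;
  if (p > 1) {
    off_mean = (accu(abs(S)) - accu(abs(S.diag()))) / double(p * (p - 1));
  }
  double thr = tol * std::max(off_mean, 1e-12);

  bool converged = (p == 1);
  int iter_used = 0;

  for (int iter = 0; iter < max_iter && !converged; ++iter) {
    double max_delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      vec beta = B.col(j);
      beta(j) = 0.0;
      // v = W * beta, maintained incrementally during coordinate descent
      vec v = W * beta;
      for (int cd = 0; cd < cd_max_iter; ++cd) {
        double cd_delta = 0.0;
        for (uword k = 0; k < p; ++k) {
          if (k == j) continue;
          double old = beta(k);
          // partial residual: S_kj - sum_{l != k,j} W_kl beta_l
          double grad = S(k, j) - (v(k) - W(k, k) * old);
          double bnew = soft_threshold(grad, Lambda(k, j)) / W(k, k);
          if (bnew != old) {
            double d = bnew - old;
            beta(k) = bnew;
            v += d * W.col(k);
            double ad = std::abs(d);
            if (ad > cd_delta) cd_delta = ad;
          }
        }
        if (cd_delta < cd_tol) break;
      }
      B.col(j) = beta;
      // w12 = W11 beta; since beta(j) = 0 this is (W beta) restricted to k != j
      vec w12 = W * beta;
      for (uword k = 0; k < p; ++k) {
        if (k == j) continue;
        double d = std::abs(w12(k) - W(k, j));
        if (d > max_delta) max_delta = d;
        W(k, j) = w12(k);
        W(j, k) = w12(k);
      }
    }
    iter_used = iter + 1;
    if (max_delta < thr) converged = true;
  }

  // recover Theta from (W, B): theta_jj = 1/(W_jj - w12' beta), theta_.j = -beta theta_jj
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    vec beta = B.col(j);
    beta(j) = 0.0;
    double denom = W(j, j) - dot(W.col(j), beta);
    if (denom <= 0)
      Rcpp::stop("graphical lasso produced a non-positive pivot; input covariance may not be positive definite");
    double tjj = 1.0 / denom;
    Theta(j, j) = tjj;
    for (uword k = 0; k < p; ++k) {
      if (k != j) Theta(k, j) = -beta(k) * tjj;
    }
  }
  // exact zeros are preserved: both triangles are zero wherever beta was zero
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(
      Rcpp::Named("Theta") = Theta,
      Rcpp::Named("W") = W,
      Rcpp::Named("B") = B,
      Rcpp::Named("iterations") = iter_used,
      Rcpp::Named("converged") = converged);
}
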