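#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cyclic coordinate descent for the weighted-lasso path using covariance
// updates.  Minimises, for each lambda (assumed non-increasing, warm starts),
//   sum_i w_i (y_i - x_i' beta)^2 + lambda * ||beta||_1
// given the precomputed Gram pieces XtWX = X' diag(w) X and XtWy = X' W y
// (X and y already centred/standardised by the caller).  The subgradient
// update for coordinate j is beta_j = S(g_j, lambda/2) / XtWX_jj with
// g_j = XtWy_j - sum_{k != j} XtWX_jk beta_k.
// [[Rcpp::export]]
arma::mat cd_lasso_cov(const arma::mat& XtWX, const arma::vec& XtWy,
                       const arma::vec& lambda, double tol, int maxit) {
  const int p = XtWX.n_rows;
  const int L = lambda.n_elem;
  arma::mat betas(p, L, arma::fill::zeros);
  arma::vec beta(p, arma::fill::zeros);
  arma::vec grad = XtWy;  // XtWy - XtWX * beta, maintained incrementally

  for (int l = 0; l < L; ++l) {
    const double thr = lambda[l] / 2.0;
    for (int it = 0; it < maxit; ++it) {
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double djj = XtWX(j, j);
        if (djj <= 0.0) { beta[j] = 0.0; continue; }
        const double gj = grad[j] + djj * beta[j];
        const double bj = soft_threshold(gj, thr) / djj;
        const double delta = bj - beta[j];
        if (delta != 0.0) {
          grad -= XtWX.col(j) * delta;
          beta[j] = bj;
          const double scaled = std::abs(delta) * std::sqrt(djj);
          if (scaled > max_delta) max_delta = scaled;
        }
      }
      if (max_delta < tol) break;
    }
    betas.col(l) = beta;
  }
  return betas;
}
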