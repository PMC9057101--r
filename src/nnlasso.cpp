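#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Cyclic coordinate descent for L1-penalised least squares with coefficients
// clamped at zero. Objective: 1/(2n) ||y - Z beta||^2 + lambda * sum(beta),
// beta >= 0. No intercept: callers supply centred/standardised data.
static void cd_fit(const mat& Z, const vec& y, const vec& colssq_n,
                   double lambda, vec& beta, vec& resid,
                   double tol, int max_iter) {
  const double n = (double) Z.n_rows;
  const uword p = Z.n_cols;
  for (int it = 0; it < max_iter; ++it) {
    double delta_max = 0.0;
    for (uword j = 0; j < p; ++j) {
      if (colssq_n(j) <= 0) { beta(j) = 0; continue; }
      const double bj = beta(j);
      const double rho = dot(Z.col(j), resid) / n + colssq_n(j) * bj;
      double bnew = (rho - lambda) / colssq_n(j);
      if (bnew < 0) bnew = 0;
      if (bnew != bj) {
        resid -= Z.col(j) * (bnew - bj);
        beta(j) = bnew;
        const double d = std::abs(bnew - bj);
        if (d > delta_max) delta_max = d;
      }
    }
    if (delta_max < tol) break;
  }
}

// Fit the whole lambda path (warm starts, lambda visited in decreasing
// order). Returns p x L coefficient matrix in the order of `lambda`.
// [[Rcpp::export(name = ".cpp_nnlasso_path")]]
arma::mat cpp_nnlasso_path(const arma::mat& Z, const arma::vec& y,
                           const arma::vec& lambda,
                           double tol = 1e-8, int max_iter = 2000) {
  const uword p = Z.n_cols, L = lambda.n_elem;
  const double n = (double) Z.n_rows;
  vec colssq_n(p);
  for (uword j = 0; j < p; ++j) colssq_n(j) = dot(Z.col(j), Z.col(j)) / n;
  uvec ord = sort_index(lambda, "descend");
  mat betas(p, L, fill::zeros);
  vec beta(p, fill::zeros), resid = y;
  for (uword s = 0; s < L; ++s) {
    const uword idx = ord(s);
    cd_fit(Z, y, colssq_n, lambda(idx), beta, resid, tol, max_iter);
    betas.col(idx) = beta;
  }
  return betas;
}

// K-fold CV squared error: returns L x nfolds matrix of held-out MSE.
// `fold` is 1-based fold membership per observation.
// [[Rcpp::export(name = ".cpp_nnlasso_cv")]]
arma::mat cpp_nnlasso_cv(const arma::mat& Z, const arma::vec& y,
                         const arma::vec& lambda, const arma::ivec& fold,
                         int nfolds, double tol = 1e-8, int max_iter = 2000) {
  const uword L = lambda.n_elem;
  mat mse(L, (uword) nfolds, fill::zeros);
  for (int f = 1; f <= nfolds; ++f) {
    uvec test = find(fold == f);
    uvec train = find(fold != f);
    if (test.n_elem == 0 || train.n_elem == 0)
      Rcpp::stop("empty cross-validation fold");
    mat Ztr = Z.rows(train), Zte = Z.rows(test);
    vec ytr = y.elem(train), yte = y.elem(test);
    mat betas = cpp_nnlasso_path(Ztr, ytr, lambda, tol, max_iter);
    for (uword l = 0; l < L; ++l) {
      vec pred = Zte * betas.col(l);
      mse(l, f - 1) = mean(square(yte - pred));
    }
  }
  return mse;
}
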