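// Successive projections algorithm: greedy orthogonal-projection chains and
// the all-starts scan with validation-RMSE subset sizing.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// One SPA chain from a given start column (0-based). Columns are projected
// onto the orthogonal complement of the selected span; at each step the
// column with the largest residual norm is appended (greedy Gram-Schmidt
// pivoting). Chains truncate when every remaining residual norm^2 falls
// below tol2.
static std::vector<uword> chain_core(const mat& X, uword start, uword k,
                                     double tol2, mat& Q, mat& W, vec& z,
                                     const vec& ycal, bool with_y) {
  const uword n = X.n_rows, p = X.n_cols;
  vec norms2 = sum(square(X), 0).t();
  std::vector<uword> sel;
  sel.reserve(k);
  uword current = start;
  for (uword s = 0; s < k; ++s) {
    vec q = X.col(current);
    for (uword i = 0; i < s; ++i)
      q -= Q.col(i) * dot(Q.col(i), q);
    double nq = norm(q);
    if (nq * nq <= tol2) break;
    q /= nq;
    Q.col(s) = q;
    rowvec w = q.t() * X;
    W.row(s) = w;
    if (with_y) z(s) = dot(q, ycal);
    sel.push_back(current);
    norms2 -= square(w.t());
    for (uword i = 0; i < sel.size(); ++i) norms2(sel[i]) = -1.0;
    if (s + 1 < k) {
      uword nxt = norms2.index_max();
      if (norms2(nxt) <= tol2) break;
      current = nxt;
    }
  }
  (void)n; (void)p;
  return sel;
}

// [[Rcpp::export(name = ".spaChainCpp")]]
Rcpp::IntegerVector spa_chain_cpp(const arma::mat& X, int start, int k, double tol) {
  const uword kk = std::min<uword>(std::min<uword>(k, X.n_rows), X.n_cols);
  mat Q(X.n_rows, kk), W(kk, X.n_cols);
  vec z(kk), dummy;
  std::vector<uword> sel =
      chain_core(X, (uword)(start - 1), kk, tol * tol, Q, W, z, dummy, false);
  Rcpp::IntegerVector out(sel.size());
  for (size_t i = 0; i < sel.size(); ++i) out[i] = (int)sel[i] + 1;
  return out;
}

// validation RMSE for every chain prefix, via back-substitution on the
// Gram-Schmidt triangle accumulated during the chain
static vec prefix_rmse(const std::vector<uword>& sel, const mat& W, const vec& z,
                       const mat& Xval, const vec& yval, double ycalMean) {
  const uword m = sel.size();
  vec out(m);
  mat R(m, m, fill::zeros);
  for (uword i = 0; i < m; ++i)
    for (uword j = i; j < m; ++j) R(i, j) = W(i, sel[j]);
  for (uword sz = 1; sz <= m; ++sz) {
    vec beta = solve(trimatu(R.submat(0, 0, sz - 1, sz - 1)), z.head(sz));
    vec pred(Xval.n_rows, fill::zeros);
    for (uword j = 0; j < sz; ++j) pred += Xval.col(sel[j]) * beta(j);
    pred += ycalMean;
    out(sz - 1) = std::sqrt(mean(square(yval - pred)));
  }
  return out;
}

// [[Rcpp::export(name = ".spaScanCpp")]]
Rcpp::List spa_scan_cpp(const arma::mat& Xcal, const arma::vec& ycalCentred,
                        double ycalMean, const arma::mat& Xval,
                        const arma::vec& yval, int maxVars, double tol) {
  const uword p = Xcal.n_cols;
  const uword k = std::min<uword>(std::min<uword>(maxVars, Xcal.n_rows - 1), p);
  const double tol2 = tol * tol;
  double bestRMSE = datum::inf;
  uword bestStart = 0, bestSize = 0;
  mat Q(Xcal.n_rows, k), W(k, p);
  vec z(k);
  for (uword start = 0; start < p; ++start) {
    if (start % 64 == 0) Rcpp::checkUserInterrupt();
    std::vector<uword> sel =
        chain_core(Xcal, start, k, tol2, Q, W, z, ycalCentred, true);
    if (sel.empty()) continue;
    vec rmse = prefix_rmse(sel, W, z, Xval, yval, ycalMean);
    for (uword sz = 1; sz <= sel.size(); ++sz) {
      double r = rmse(sz - 1);
      if (!std::isfinite(r)) continue;
      if (!std::isfinite(bestRMSE)) {
        bestRMSE = r; bestStart = start; bestSize = sz;
        continue;
      }
      double slack = 1e-12 * std::max(1.0, bestRMSE);
      bool better = r < bestRMSE - slack;
      bool tie = std::abs(r - bestRMSE) <= slack;
      if (better ||
          (tie && (sz < bestSize || (sz == bestSize && start < bestStart)))) {
        bestRMSE = r;
        bestStart = start;
        bestSize = sz;
      }
    }
  }
  if (!std::isfinite(bestRMSE))
    Rcpp::stop("SPA scan failed: no usable chain (all columns collinear?)");
  std::vector<uword> sel =
      chain_core(Xcal, bestStart, k, tol2, Q, W, z, ycalCentred, true);
  vec rmse = prefix_rmse(sel, W, z, Xval, yval, ycalMean);
  Rcpp::IntegerVector chain(sel.size());
  for (size_t i = 0; i < sel.size(); ++i) chain[i] = (int)sel[i] + 1;
  return Rcpp::List::create(
      Rcpp::Named("start") = (int)bestStart + 1,
      Rcpp::Named("size") = (int)bestSize,
      Rcpp::Named("chain") = chain,
      Rcpp::Named("rmseCurve") = rmse,
      Rcpp::Named("bestRMSE") = bestRMSE);
}
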