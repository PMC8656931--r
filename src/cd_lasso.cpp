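#include <Rcpp.h>
using namespace Rcpp;

// Coordinate descent for the weighted lasso subproblem of the penalized
// Cox IRLS loop:
//   minimize (1/(2n)) sum_i w_i (z_i - x_i'b)^2 + sum_j lam_j |b_j|
// X is the (already standardized) design; lam carries the per-coefficient
// penalty (SCAD derivative under local linear approximation). Active-set
// iteration: full sweeps establish the working set, inner sweeps iterate
// it to convergence.

static double sweepSet(const NumericMatrix& X, const NumericVector& w,
                       const std::vector<double>& xtx,
                       const NumericVector& lam,
                       const std::vector<int>& idx,
                       NumericVector& beta, std::vector<double>& r) {
  const int n = X.nrow();
  double maxdiff = 0.0;
  for (int jj = (int)idx.size() - 1; jj >= 0; --jj) {
    const int j = idx[jj];
    if (xtx[j] <= 1e-12) continue;
    double num = 0.0;
    for (int i = 0; i < n; ++i) num += w[i] * X(i, j) * r[i];
    num = num / n + xtx[j] * beta[j];
    const double l = lam[j];
    double bnew;
    if (num > l)       bnew = (num - l) / xtx[j];
    else if (num < -l) bnew = (num + l) / xtx[j];
    else               bnew = 0.0;
    const double d = bnew - beta[j];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
      const double ad = d < 0 ? -d : d;
      if (ad > maxdiff) maxdiff = ad;
      beta[j] = bnew;
    }
  }
  return maxdiff;
}

// [[Rcpp::export]]
NumericVector cdWeightedLasso(const NumericMatrix& X,
                              const NumericVector& w,
                              const NumericVector& z,
                              const NumericVector& lam,
                              const NumericVector& betaInit,
                              double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector beta = clone(betaInit);
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int j = 0; j < p; ++j)
      if (beta[j] != 0.0) eta += X(i, j) * beta[j];
    r[i] = z[i] - eta;
  }
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += w[i] * X(i, j) * X(i, j);
    xtx[j] = s / n;
  }
  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;
  int sweeps = 0;
  while (sweeps < maxit) {
    ++sweeps;
    double mdFull = sweepSet(X, w, xtx, lam, all, beta, r);
    if (mdFull < tol) break;
    std::vector<int> active;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
    while (sweeps < maxit) {
      ++sweeps;
      if (sweepSet(X, w, xtx, lam, active, beta, r) < tol) break;
    }
  }
  return beta;
}
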