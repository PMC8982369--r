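#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for
//   min_b ||y - X b||^2 + lambda2 ||b||^2 + lambda1 ||b||_1
// (no 1/n factors; the intercept is handled by the caller via centering).
// Update: b_j = soft(x_j' (r + x_j b_j), lambda1 / 2) / (x_j' x_j + lambda2).
// Converged when the largest coefficient change in a sweep is < tol.
// [[Rcpp::export(name = ".enet_cd")]]
List enet_cd(const NumericMatrix& X, const NumericVector& y,
             double lambda1, double lambda2,
             NumericVector beta_init, double tol = 1e-7,
             int max_sweeps = 10000) {
  const int n = X.nrow(), m = X.ncol();
  NumericVector beta = clone(beta_init);
  NumericVector r(n);
  for (int i = 0; i < n; ++i) {
    double fit = 0.0;
    for (int j = 0; j < m; ++j) fit += X(i, j) * beta[j];
    r[i] = y[i] - fit;
  }
  std::vector<double> xx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xx[j] = s;
  }
  const double thr = lambda1 / 2.0;
  bool converged = false;
  int sweep = 0;
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_change = 0.0;
    for (int j = 0; j < m; ++j) {
      if (xx[j] + lambda2 <= 0.0) { beta[j] = 0.0; continue; }
      double rho = 0.0;
      for (int i = 0; i < n; ++i) rho += X(i, j) * r[i];
      rho += xx[j] * beta[j];
      double bj;
      if (rho > thr) bj = (rho - thr) / (xx[j] + lambda2);
      else if (rho < -thr) bj = (rho + thr) / (xx[j] + lambda2);
      else bj = 0.0;
      double diff = bj - beta[j];
      if (diff != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * diff;
        beta[j] = bj;
        double ad = std::fabs(diff);
        if (ad > max_change) max_change = ad;
      }
    }
    if (max_change < tol) { converged = true; ++sweep; break; }
  }
  return List::create(_["beta"] = beta, _["converged"] = converged,
                      _["sweeps"] = sweep);
}
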