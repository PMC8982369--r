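#include <Rcpp.h>
using namespace Rcpp;

// BayesB Gibbs sampler. Mixture prior on marker effects: with probability pi
// the effect is exactly zero; otherwise beta_k ~ N(0, sigma_gk^2) with
// sigma_gk^2 ~ scaled-inv-chi-square(nu, s2) -- marginally a scaled-t prior.
// The inclusion indicator is sampled from its full conditional by integrating
// beta_k out given sigma_gk^2:
//   BF(in vs out) = sqrt(lam/(c+lam)) * exp(rhs^2 / (2 sigma_e^2 (c+lam))),
// lam = sigma_e^2 / sigma_gk^2, c = z_k'z_k, rhs = z_k' r_k.
// Uses R's RNG, so results are reproducible via set.seed() in R.
// [[Rcpp::export(name = ".bayesb_mcmc")]]
List bayesb_mcmc(const NumericMatrix& Z, const NumericVector& y,
                 int n_iter, int burn_in, int thin,
                 double pi_null, double nu, double s2,
                 double nu_e, double s2_e) {
  const int n = Z.nrow(), m = Z.ncol();
  RNGScope scope;
  std::vector<double> beta(m, 0.0), sig_g(m, s2), zz(m);
  std::vector<int> incl(m, 0);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    zz[j] = s;
  }
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double mu = ybar, sig_e = s2_e;
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  std::vector<double> beta_sum(m, 0.0), incl_sum(m, 0.0);
  double mu_sum = 0.0, sige_sum = 0.0;
  int kept = 0;
  const double log_prior_odds = std::log(1.0 - pi_null) - std::log(pi_null);

  for (int it = 1; it <= n_iter; ++it) {
    for (int j = 0; j < m; ++j) {
      if (zz[j] <= 0.0) continue;
      // full-conditional residual for marker j
      double rhs = 0.0;
      if (beta[j] != 0.0) {
        for (int i = 0; i < n; ++i) { r[i] += Z(i, j) * beta[j]; }
      }
      for (int i = 0; i < n; ++i) rhs += Z(i, j) * r[i];
      double lam = sig_e / sig_g[j];
      double c = zz[j];
      double log_bf = 0.5 * std::log(lam / (c + lam)) +
        rhs * rhs / (2.0 * sig_e * (c + lam));
      double log_odds = log_prior_odds + log_bf;
      double p_in = (pi_null <= 0.0) ? 1.0 :
        (pi_null >= 1.0 ? 0.0 : 1.0 / (1.0 + std::exp(-log_odds)));
      bool in = (unif_rand() < p_in);
      if (in) {
        double v = sig_e / (c + lam);
        double b = rhs / (c + lam) + std::sqrt(v) * norm_rand();
        beta[j] = b;
        incl[j] = 1;
        for (int i = 0; i < n; ++i) r[i] -= Z(i, j) * b;
        sig_g[j] = (nu * s2 + b * b) / Rf_rchisq(nu + 1.0);
      } else {
        beta[j] = 0.0;
        incl[j] = 0;
        sig_g[j] = nu * s2 / Rf_rchisq(nu); // fresh draw from the prior
      }
    }
    // intercept
    double rbar = 0.0;
    for (int i = 0; i < n; ++i) rbar += r[i] + mu;
    rbar /= n;
    double mu_new = rbar + std::sqrt(sig_e / n) * norm_rand();
    for (int i = 0; i < n; ++i) r[i] += mu - mu_new;
    mu = mu_new;
    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += r[i] * r[i];
    sig_e = (nu_e * s2_e + sse) / Rf_rchisq(nu_e + n);
    if (!R_finite(sig_e) || sig_e <= 0.0) {
      stop("MCMC failure: non-finite residual variance at iteration %d", it);
    }
    if (it > burn_in && (it - burn_in) % thin == 0) {
      ++kept;
      for (int j = 0; j < m; ++j) {
        beta_sum[j] += beta[j];
        incl_sum[j] += incl[j];
      }
      mu_sum += mu;
      sige_sum += sig_e;
    }
  }
  NumericVector beta_mean(m), incl_freq(m);
  for (int j = 0; j < m; ++j) {
    beta_mean[j] = beta_sum[j] / kept;
    incl_freq[j] = incl_sum[j] / kept;
  }
  return List::create(_["beta"] = beta_mean, _["inclusion"] = incl_freq,
                      _["mu"] = mu_sum / kept, _["sigma_e"] = sige_sum / kept,
                      _["n_samples"] = kept);
}
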