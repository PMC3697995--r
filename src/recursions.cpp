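#include <Rcpp.h>
using namespace Rcpp;

// Conditional (zero-initialised) ARMA residual recursion on deviations from mu.
// eps_t = d_t - sum_i phi_i d_{t-li} - sum_j theta_j eps_{t-lj}, d_t = x_t - mu,
// with d and eps taken as 0 before the sample starts.
// [[Rcpp::export]]
NumericVector arma_css_resid_cpp(NumericVector x, double mu,
                                 IntegerVector ar_lags, NumericVector ar_coefs,
                                 IntegerVector ma_lags, NumericVector ma_coefs) {
  int n = x.size();
  NumericVector eps(n);
  for (int t = 0; t < n; ++t) {
    double e = x[t] - mu;
    for (int i = 0; i < ar_lags.size(); ++i) {
      int l = ar_lags[i];
      if (t - l >= 0) e -= ar_coefs[i] * (x[t - l] - mu);
    }
    for (int j = 0; j < ma_lags.size(); ++j) {
      int l = ma_lags[j];
      if (t - l >= 0) e -= ma_coefs[j] * eps[t - l];
    }
    eps[t] = e;
  }
  return eps;
}

// GARCH(m,k) conditional-variance recursion.
// sigma2_t = gamma0 + sum_i gamma_i eps2_{t-i} + sum_j delta_j sigma2_{t-j};
// pre-sample eps2 and sigma2 are set to `init` (typically the sample mean of eps2).
// [[Rcpp::export]]
NumericVector garch_filter_cpp(NumericVector eps2, double gamma0,
                               NumericVector gamma, NumericVector delta,
                               double init) {
  int n = eps2.size();
  NumericVector s2(n);
  for (int t = 0; t < n; ++t) {
    double v = gamma0;
    for (int i = 0; i < gamma.size(); ++i) {
      int l = i + 1;
      v += gamma[i] * (t - l >= 0 ? eps2[t - l] : init);
    }
    for (int j = 0; j < delta.size(); ++j) {
      int l = j + 1;
      v += delta[j] * (t - l >= 0 ? s2[t - l] : init);
    }
    s2[t] = v;
  }
  return s2;
}

// Simulate an ARMA process with (G)ARCH innovations from pre-drawn iid
// unit-variance shocks e. Returns the ARMA path (deviations around zero);
// burn-in is discarded by the caller.
// [[Rcpp::export]]
List arma_garch_sim_cpp(NumericVector e,
                        IntegerVector ar_lags, NumericVector ar_coefs,
                        IntegerVector ma_lags, NumericVector ma_coefs,
                        double gamma0, NumericVector gamma, NumericVector delta) {
  int n = e.size();
  NumericVector eps(n), s2(n), x(n);
  double denom = 1.0 - sum(gamma) - sum(delta);
  double init = denom > 1e-8 ? gamma0 / denom : gamma0; // stationary variance if it exists
  for (int t = 0; t < n; ++t) {
    double v = gamma0;
    for (int i = 0; i < gamma.size(); ++i) {
      int l = i + 1;
      v += gamma[i] * (t - l >= 0 ? eps[t - l] * eps[t - l] : init);
    }
    for (int j = 0; j < delta.size(); ++j) {
      int l = j + 1;
      v += delta[j] * (t - l >= 0 ? s2[t - l] : init);
    }
    s2[t] = v;
    eps[t] = e[t] * std::sqrt(v);
    double xt = eps[t];
    for (int i = 0; i < ar_lags.size(); ++i) {
      int l = ar_lags[i];
      if (t - l >= 0) xt += ar_coefs[i] * x[t - l];
    }
    for (int j = 0; j < ma_lags.size(); ++j) {
      int l = ma_lags[j];
      if (t - l >= 0) xt += ma_coefs[j] * eps[t - l];
    }
    x[t] = xt;
  }
  return List::create(_["x"] = x, _["eps"] = eps, _["sigma2"] = s2);
}

// Monte-Carlo EWMA run lengths with asymptotic-variance limits.
// Observations x ~ N(delta, 1); z0 = 0; signal when |z| > L*sqrt(lambda/(2-lambda)).
// Uses R's RNG so set.seed() on the R side makes runs reproducible.
// [[Rcpp::export]]
NumericVector ewma_run_lengths_cpp(double lambda, double L, double delta,
                                   int reps, int max_len) {
  NumericVector rl(reps);
  double lim = L * std::sqrt(lambda / (2.0 - lambda));
  for (int r = 0; r < reps; ++r) {
    double z = 0.0;
    int t = 0;
    while (t < max_len) {
      ++t;
      z = lambda * (delta + norm_rand()) + (1.0 - lambda) * z;
      if (z > lim || z < -lim) break;
    }
    rl[r] = t;
  }
  return rl;
}
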