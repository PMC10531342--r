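#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double LOG_SQRT_2PI = 0.9189385332046727417803297;

// One EM run for a univariate Gaussian mixture with a sigma floor.
// Responsibilities are streamed per observation so memory stays O(K).
// Returns the fitted parameters, the log-likelihood trace (one value per
// iteration, evaluated at the parameters entering the iteration), the final
// log-likelihood of the returned parameters, and the largest decrease seen
// between consecutive trace values (monitoring EM monotonicity).
// [[Rcpp::export]]
List em_gmm_cpp(NumericVector x, NumericVector w0, NumericVector mu0,
                NumericVector sigma0, double sigma_min, double tol,
                int max_iter) {
  const int n = x.size();
  const int K = w0.size();
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sig(sigma0.begin(), sigma0.end());
  for (int k = 0; k < K; ++k) if (sig[k] < sigma_min) sig[k] = sigma_min;

  std::vector<double> logw(K), Nk(K), Sx(K), Sxx(K), lp(K);
  std::vector<double> trace;
  trace.reserve(64);
  double prev_ll = R_NegInf, max_decrease = 0.0;
  bool converged = false;
  int iter = 0;

  auto pass = [&](bool accumulate) -> double {
    for (int k = 0; k < K; ++k) {
      logw[k] = std::log(w[k] > 1e-300 ? w[k] : 1e-300) - std::log(sig[k]) -
                LOG_SQRT_2PI;
      Nk[k] = Sx[k] = Sxx[k] = 0.0;
    }
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      const double xi = x[i];
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        const double z = (xi - mu[k]) / sig[k];
        lp[k] = logw[k] - 0.5 * z * z;
        if (lp[k] > m) m = lp[k];
      }
      double se = 0.0;
      for (int k = 0; k < K; ++k) {
        lp[k] = std::exp(lp[k] - m);
        se += lp[k];
      }
      ll += m + std::log(se);
      if (accumulate) {
        for (int k = 0; k < K; ++k) {
          const double r = lp[k] / se;
          Nk[k] += r;
          Sx[k] += r * xi;
          Sxx[k] += r * xi * xi;
        }
      }
    }
    return ll;
  };

  for (iter = 0; iter < max_iter; ++iter) {
    const double ll = pass(true);
    trace.push_back(ll);
    if (iter > 0) {
      if (prev_ll - ll > max_decrease) max_decrease = prev_ll - ll;
      if (std::fabs(ll - prev_ll) <=
          tol * (std::fabs(prev_ll) + 1e-12)) {
        converged = true;
        break;
      }
    }
    prev_ll = ll;
    // M step with the sigma floor; a dying component keeps its location
    for (int k = 0; k < K; ++k) {
      if (Nk[k] > 1e-10) {
        const double m1 = Sx[k] / Nk[k];
        double v = Sxx[k] / Nk[k] - m1 * m1;
        if (v < 0.0) v = 0.0;
        mu[k] = m1;
        sig[k] = std::sqrt(v);
      }
      if (sig[k] < sigma_min) sig[k] = sigma_min;
      w[k] = Nk[k] / n;
      if (w[k] < 1e-12) w[k] = 1e-12;
    }
    double sw = 0.0;
    for (int k = 0; k < K; ++k) sw += w[k];
    for (int k = 0; k < K; ++k) w[k] /= sw;
  }

  const double final_ll = pass(false);
  return List::create(
      _["weights"] = NumericVector(w.begin(), w.end()),
      _["means"] = NumericVector(mu.begin(), mu.end()),
      _["sigmas"] = NumericVector(sig.begin(), sig.end()),
      _["logLik"] = final_ll,
      _["trace"] = NumericVector(trace.begin(), trace.end()),
      _["iterations"] = (int)trace.size(),
      _["converged"] = converged,
      _["maxDecrease"] = max_decrease);
}

// Mixture log-likelihood of `x` under (w, mu, sigma), log-sum-exp guarded.
// [[Rcpp::export]]
double gmm_loglik_cpp(NumericVector x, NumericVector w, NumericVector mu,
                      NumericVector sigma) {
  const int n = x.size(), K = w.size();
  std::vector<double> logw(K), lp(K);
  for (int k = 0; k < K; ++k) {
    logw[k] = std::log(w[k] > 1e-300 ? w[k] : 1e-300) - std::log(sigma[k]) -
              LOG_SQRT_2PI;
  }
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double m = R_NegInf;
    for (int k = 0; k < K; ++k) {
      const double z = (x[i] - mu[k]) / sigma[k];
      lp[k] = logw[k] - 0.5 * z * z;
      if (lp[k] > m) m = lp[k];
    }
    double se = 0.0;
    for (int k = 0; k < K; ++k) se += std::exp(lp[k] - m);
    ll += m + std::log(se);
  }
  return ll;
}
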