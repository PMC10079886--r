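#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// IIR filter, transposed direct-form II, with explicit initial state.
// b and a must be same length (pad with zeros); a[0] == 1 assumed after
// normalisation on the R side.
// [[Rcpp::export]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a,
                          NumericVector x, NumericVector zi) {
  int nf = std::max(b.size(), a.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0), z(nf - 1, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  for (int i = 0; i < nf - 1 && i < zi.size(); ++i) z[i] = zi[i];
  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nf - 2; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}

// One EM run for a univariate two-component Gaussian mixture, started from
// responsibilities for component 2. Each iteration does the M-step first,
// then an E-step that also evaluates the observed-data log-likelihood of
// the freshly updated parameters, so the recorded trace is the textbook
// monotone sequence. Convergence: change in mean per-sample log-likelihood
// below tol.
// [[Rcpp::export]]
List em_run_cpp(NumericVector x, NumericVector gamma2,
                double tol, int max_iter, double var_floor) {
  const int n = x.size();
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) g[i] = gamma2[i];

  double mu1 = 0, mu2 = 0, v1 = 1, v2 = 1, w2 = 0.5;
  std::vector<double> ll_trace;
  ll_trace.reserve(64);
  double ll_old = R_NegInf;
  bool converged = false, degenerate = false;
  int iter = 0;

  const double log2pi = std::log(2.0 * M_PI);

  for (iter = 0; iter < max_iter; ++iter) {
    // ---- M-step from current responsibilities
    double s2 = 0, sx1 = 0, sx2 = 0;
    for (int i = 0; i < n; ++i) {
      s2 += g[i];
      sx2 += g[i] * x[i];
      sx1 += (1.0 - g[i]) * x[i];
    }
    double s1 = n - s2;
    if (s1 < 1e-10 || s2 < 1e-10) { degenerate = true; break; }
    mu1 = sx1 / s1;
    mu2 = sx2 / s2;
    double q1 = 0, q2 = 0;
    for (int i = 0; i < n; ++i) {
      double d1 = x[i] - mu1, d2 = x[i] - mu2;
      q1 += (1.0 - g[i]) * d1 * d1;
      q2 += g[i] * d2 * d2;
    }
    v1 = q1 / s1; if (v1 < var_floor) v1 = var_floor;
    v2 = q2 / s2; if (v2 < var_floor) v2 = var_floor;
    w2 = s2 / n;                      // w1 = 1 - w2 exactly

    // ---- E-step + log-likelihood of the updated parameters
    double lw1 = std::log(1.0 - w2), lw2 = std::log(w2);
    double c1 = -0.5 * (log2pi + std::log(v1));
    double c2 = -0.5 * (log2pi + std::log(v2));
    double ll = 0;
    for (int i = 0; i < n; ++i) {
      double d1 = x[i] - mu1, d2 = x[i] - mu2;
      double l1 = lw1 + c1 - 0.5 * d1 * d1 / v1;
      double l2 = lw2 + c2 - 0.5 * d2 * d2 / v2;
      double m = l1 > l2 ? l1 : l2;
      double lse = m + std::log(std::exp(l1 - m) + std::exp(l2 - m));
      ll += lse;
      g[i] = std::exp(l2 - lse);
    }
    ll_trace.push_back(ll);
    if (iter > 0 && (ll - ll_old) / n < tol) {
      converged = true;
      ++iter;
      break;
    }
    ll_old = ll;
  }

  return List::create(
    _["mu1"] = mu1, _["mu2"] = mu2,
    _["sigma1"] = std::sqrt(v1), _["sigma2"] = std::sqrt(v2),
    _["w2"] = w2,
    _["log_likelihood"] = ll_trace.empty() ? R_NegInf : ll_trace.back(),
    _["loglik_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
    _["n_iter"] = (int)ll_trace.size(),
    _["converged"] = converged,
    _["degenerate"] = degenerate);
}
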