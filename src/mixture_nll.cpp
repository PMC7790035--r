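#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Negative log-likelihood of paired z-scores under a zero-mean K-component
// bivariate Gaussian mixture. w: component weights (sum 1); sa, sb:
// per-component marginal variances; cab: per-component covariances.
// Evaluated with a per-observation log-sum-exp so that far-tail points do
// not underflow to zero density.
// [[Rcpp::export]]
double bivariate_mixture_nll_cpp(NumericVector za, NumericVector zb,
                                 NumericVector w, NumericVector sa,
                                 NumericVector sb, NumericVector cab) {
  const int n = za.size();
  const int K = w.size();
  std::vector<double> ia(K), ib(K), ic(K), logwn(K);
  std::vector<int> act;
  for (int k = 0; k < K; ++k) {
    double det = sa[k] * sb[k] - cab[k] * cab[k];
    if (!(det > 0.0) || sa[k] <= 0.0 || sb[k] <= 0.0) return R_PosInf;
    if (w[k] <= 0.0) continue;
    ia[k] = sb[k] / det;
    ib[k] = sa[k] / det;
    ic[k] = -cab[k] / det;
    logwn[k] = std::log(w[k]) - std::log(2.0 * M_PI) - 0.5 * std::log(det);
    act.push_back(k);
  }
  if (act.empty()) return R_PosInf;
  double nll = 0.0;
  std::vector<double> lk(act.size());
  for (int j = 0; j < n; ++j) {
    const double x = za[j], y = zb[j];
    double mx = R_NegInf;
    for (size_t a = 0; a < act.size(); ++a) {
      const int k = act[a];
      lk[a] = logwn[k] -
              0.5 * (ia[k] * x * x + ib[k] * y * y + 2.0 * ic[k] * x * y);
      if (lk[a] > mx) mx = lk[a];
    }
    double s = 0.0;
    for (size_t a = 0; a < act.size(); ++a) s += std::exp(lk[a] - mx);
    nll -= mx + std::log(s);
  }
  return nll;
}

// Univariate analogue: z under sum_k w_k N(0, s2_k).
// [[Rcpp::export]]
double univariate_mixture_nll_cpp(NumericVector z, NumericVector w,
                                  NumericVector s2) {
  const int n = z.size();
  const int K = w.size();
  std::vector<double> inv(K), logwn(K);
  std::vector<int> act;
  for (int k = 0; k < K; ++k) {
    if (s2[k] <= 0.0) return R_PosInf;
    if (w[k] <= 0.0) continue;
    inv[k] = 1.0 / s2[k];
    logwn[k] = std::log(w[k]) - 0.5 * std::log(2.0 * M_PI * s2[k]);
    act.push_back(k);
  }
  if (act.empty()) return R_PosInf;
  double nll = 0.0;
  std::vector<double> lk(act.size());
  for (int j = 0; j < n; ++j) {
    const double x = z[j];
    double mx = R_NegInf;
    for (size_t a = 0; a < act.size(); ++a) {
      const int k = act[a];
      lk[a] = logwn[k] - 0.5 * inv[k] * x * x;
      if (lk[a] > mx) mx = lk[a];
    }
    double s = 0.0;
    for (size_t a = 0; a < act.size(); ++a) s += std::exp(lk[a] - mx);
    nll -= mx + std::log(s);
  }
  return nll;
}
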