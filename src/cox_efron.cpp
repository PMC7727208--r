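#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Efron-corrected Cox log partial likelihood.
//
// Risk set at an event time t is everyone with observed time >= t
// (censored observations tied with an event remain at risk). For a
// tied block of d events with risk-set total R and tied total s, the
// Efron contribution is sum(eta_events) - sum_{l=0}^{d-1} log(R - l/d * s).
//
// The likelihood is invariant to adding a constant to eta; we centre by
// the maximum before exponentiating for numerical stability.
// [[Rcpp::export]]
double cox_loglik_efron_cpp(NumericVector time, IntegerVector status,
                            NumericVector eta) {
  const int n = time.size();
  if (status.size() != n || eta.size() != n)
    stop("time, status and eta must have equal length");

  double emax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (!R_finite(eta[i])) stop("non-finite linear predictor");
    if (eta[i] > emax) emax = eta[i];
  }
  if (n == 0) return 0.0;

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  // descending time so the risk-set total accumulates as we walk forward
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return time[a] > time[b];
  });

  double ll = 0.0, risk = 0.0;
  int i = 0;
  while (i < n) {
    const double t = time[ord[i]];
    // absorb the whole tied block (events and censorings) into the risk set
    int j = i;
    double tied_s = 0.0, tied_eta = 0.0;
    int d = 0;
    while (j < n && time[ord[j]] == t) {
      const double w = std::exp(eta[ord[j]] - emax);
      risk += w;
      if (status[ord[j]] == 1) {
        tied_s += w;
        tied_eta += eta[ord[j]] - emax;
        ++d;
      }
      ++j;
    }
    if (d > 0) {
      ll += tied_eta;
      for (int l = 0; l < d; ++l)
        ll -= std::log(risk - (static_cast<double>(l) / d) * tied_s);
    }
    i = j;
  }
  return ll;
}

// Linear predictor helper: X %*% beta without allocating in R's hot loop.
// [[Rcpp::export]]
NumericVector cox_linpred_cpp(NumericMatrix X, NumericVector beta) {
  const int n = X.nrow(), p = X.ncol();
  if (beta.size() != p) stop("length(beta) must equal ncol(X)");
  NumericVector eta(n);
  for (int j = 0; j < p; ++j) {
    const double b = beta[j];
    if (b == 0.0) continue;
    for (int i = 0; i < n; ++i) eta[i] += X(i, j) * b;
  }
  return eta;
}
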