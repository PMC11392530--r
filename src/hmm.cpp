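// Scaled forward-backward for the pairwise SMC hidden Markov model.
// Generic over the observation layer: the caller supplies per-segment
// log-emission values (a segment is one site, or one fixed-width bin whose
// log-emission is the sum over its sites). Per-segment rescaling keeps the
// recursion stable on arbitrarily long sequences; posteriors are rescaled so
// each row sums to one.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".hmm_fb_cpp")]]
List hmm_fb_cpp(NumericMatrix A, NumericMatrix logE, NumericVector pi,
                bool want_posterior = false, bool want_xi = false,
                bool forward_only = false) {
  int T = logE.nrow(), S = logE.ncol();
  if (A.nrow() != S || A.ncol() != S || pi.size() != S)
    stop("dimension mismatch");
  if (T < 1) stop("empty sequence");

  NumericMatrix alpha(T, S);
  NumericVector cvec(T), rowmax(T);
  // shifted emissions: E[t,s] = exp(logE[t,s] - max_s logE[t,s])
  NumericMatrix E(T, S);
  for (int t = 0; t < T; ++t) {
    double m = logE(t, 0);
    for (int s = 1; s < S; ++s) if (logE(t, s) > m) m = logE(t, s);
    rowmax[t] = m;
    for (int s = 0; s < S; ++s) E(t, s) = std::exp(logE(t, s) - m);
  }

  // forward
  double c0 = 0;
  for (int s = 0; s < S; ++s) { alpha(0, s) = pi[s] * E(0, s); c0 += alpha(0, s); }
  if (c0 <= 0) stop("zero forward mass at position 1");
  for (int s = 0; s < S; ++s) alpha(0, s) /= c0;
  cvec[0] = c0;
  for (int t = 1; t < T; ++t) {
    double ct = 0;
    for (int s = 0; s < S; ++s) {
      double a = 0;
      for (int k = 0; k < S; ++k) a += alpha(t - 1, k) * A(k, s);
      a *= E(t, s);
      alpha(t, s) = a;
      ct += a;
    }
    if (ct <= 0) stop("zero forward mass at position ", t + 1);
    for (int s = 0; s < S; ++s) alpha(t, s) /= ct;
    cvec[t] = ct;
  }
  double loglik = 0;
  for (int t = 0; t < T; ++t) loglik += std::log(cvec[t]) + rowmax[t];

  if (forward_only) {
    return List::create(_["loglik"] = loglik);
  }

  // backward (same scaling constants)
  NumericMatrix beta(T, S);
  for (int s = 0; s < S; ++s) beta(T - 1, s) = 1.0;
  NumericMatrix xi(S, S);
  for (int t = T - 2; t >= 0; --t) {
    for (int s = 0; s < S; ++s) {
      double b = 0;
      for (int l = 0; l < S; ++l) b += A(s, l) * E(t + 1, l) * beta(t + 1, l);
      beta(t, s) = b / cvec[t + 1];
    }
    if (want_xi) {
      for (int k = 0; k < S; ++k) {
        double ak = alpha(t, k);
        if (ak == 0) continue;
        for (int l = 0; l < S; ++l)
          xi(k, l) += ak * A(k, l) * E(t + 1, l) * beta(t + 1, l) / cvec[t + 1];
      }
    }
  }

  NumericMatrix gamma;
  NumericVector gamma1(S);
  if (want_posterior) {
    gamma = NumericMatrix(T, S);
    for (int t = 0; t < T; ++t) {
      double z = 0;
      for (int s = 0; s < S; ++s) { gamma(t, s) = alpha(t, s) * beta(t, s); z += gamma(t, s); }
      for (int s = 0; s < S; ++s) gamma(t, s) /= z;
    }
    for (int s = 0; s < S; ++s) gamma1[s] = gamma(0, s);
  } else {
    double z = 0;
    for (int s = 0; s < S; ++s) { gamma1[s] = alpha(0, s) * beta(0, s); z += gamma1[s]; }
    for (int s = 0; s < S; ++s) gamma1[s] /= z;
  }

  List out = List::create(_["loglik"] = loglik, _["gamma1"] = gamma1);
  if (want_posterior) out["posterior"] = gamma;
  if (want_xi) out["xi"] = xi;
  return out;
}
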