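#include <Rcpp.h>
using namespace Rcpp;

// Fused kernels for the vectorized per-neuron readout fits: the double
// exponential r = b + a * exp(-exp(k * (y - s))) applied row-wise to a
// drive matrix, with per-row loss and gradients computed in one pass.

static inline double clip30(double z) {
  if (z > 30.0) return 30.0;
  if (z < -30.0) return -30.0;
  return z;
}

// Per-row mean squared error of the double exponential prediction.
// [[Rcpp::export]]
NumericVector cc_dexp_rowmse(NumericMatrix drive, NumericMatrix R,
                             NumericVector b, NumericVector a,
                             NumericVector s, NumericVector k) {
  int N = drive.nrow(), T = drive.ncol();
  NumericVector out(N);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < N; ++i) {
      double e1 = std::exp(clip30(k[i] * (drive(i, t) - s[i])));
      double d = b[i] + a[i] * std::exp(-e1) - R(i, t);
      out[i] += d * d;
    }
  }
  for (int i = 0; i < N; ++i) out[i] /= T;
  return out;
}

// Gradients of the summed squared error (scaled by 2 / T) w.r.t. the
// double exponential parameters and the drive. Returns a list with g_b,
// g_a, g_s, g_k (length N) and ddrive (N x T).
// [[Rcpp::export]]
List cc_dexp_grad(NumericMatrix drive, NumericMatrix R,
                  NumericVector b, NumericVector a,
                  NumericVector s, NumericVector k) {
  int N = drive.nrow(), T = drive.ncol();
  NumericVector gb(N), ga(N), gs(N), gk(N);
  NumericMatrix dd(N, T);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < N; ++i) {
      double e1 = std::exp(clip30(k[i] * (drive(i, t) - s[i])));
      double E = std::exp(-e1);
      double resid = 2.0 * (b[i] + a[i] * E - R(i, t)) / T;
      double e1E = e1 * E;
      gb[i] += resid;
      ga[i] += resid * E;
      gs[i] += resid * a[i] * k[i] * e1E;
      gk[i] -= resid * a[i] * e1E * (drive(i, t) - s[i]);
      dd(i, t) = -resid * a[i] * k[i] * e1E;
    }
  }
  return List::create(_["g_b"] = gb, _["g_a"] = ga, _["g_s"] = gs,
                      _["g_k"] = gk, _["ddrive"] = dd);
}
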