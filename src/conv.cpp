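#include <Rcpp.h>
using namespace Rcpp;

// Causal FIR convolution along time for multi-channel signals, with
// independent zero-padded segments (stimulus snippets). All indices in
// `starts` are 1-based segment start columns; the first must be 1.
// X: C x T, taps: C x U. Y[c,t] = sum_u taps[c,u] * X[c,t-u], where X is
// treated as zero before the start of the segment containing t.

static std::vector<int> segment_of(int T, const IntegerVector& starts) {
  std::vector<int> seg(T);
  int s = 0, n = starts.size();
  for (int t = 0; t < T; ++t) {
    while (s + 1 < n && t >= starts[s + 1] - 1) ++s;
    seg[t] = s;
  }
  return seg;
}

// Segment boundaries as [start, end) pairs (0-based).
static void segment_ranges(int T, const IntegerVector& starts,
                           std::vector<int>& s0, std::vector<int>& s1) {
  int n = starts.size();
  s0.resize(n); s1.resize(n);
  for (int i = 0; i < n; ++i) {
    s0[i] = starts[i] - 1;
    s1[i] = (i + 1 < n) ? (starts[i + 1] - 1) : T;
  }
}

// [[Rcpp::export]]
NumericMatrix cc_conv1d(NumericMatrix X, NumericMatrix taps, IntegerVector starts) {
  int C = X.nrow(), T = X.ncol(), U = taps.ncol();
  if (taps.nrow() != C) stop("taps rows must match signal channels");
  NumericMatrix Y(C, T);
  std::vector<int> s0, s1;
  segment_ranges(T, starts, s0, s1);
  std::vector<double> x(T), h(U), y(T);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < T; ++t) x[t] = X(c, t);
    for (int u = 0; u < U; ++u) h[u] = taps(c, u);
    for (size_t s = 0; s < s0.size(); ++s) {
      for (int t = s0[s]; t < s1[s]; ++t) {
        int umax = std::min(U - 1, t - s0[s]);
        double acc = 0.0;
        const double* xp = &x[t];
        for (int u = 0; u <= umax; ++u) acc += h[u] * xp[-u];
        y[t] = acc;
      }
    }
    for (int t = 0; t < T; ++t) Y(c, t) = y[t];
  }
  return Y;
}

// Gradient of the loss w.r.t. the input X given dL/dY (correlation with taps,
// respecting segment ends).
// [[Rcpp::export]]
NumericMatrix cc_conv1d_grad_x(NumericMatrix dY, NumericMatrix taps, IntegerVector starts) {
  int C = dY.nrow(), T = dY.ncol(), U = taps.ncol();
  NumericMatrix dX(C, T);
  std::vector<int> s0, s1;
  segment_ranges(T, starts, s0, s1);
  std::vector<double> g(T), h(U), d(T);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < T; ++t) g[t] = dY(c, t);
    for (int u = 0; u < U; ++u) h[u] = taps(c, u);
    for (size_t s = 0; s < s0.size(); ++s) {
      for (int t = s0[s]; t < s1[s]; ++t) {
        int umax = std::min(U - 1, s1[s] - 1 - t);
        double acc = 0.0;
        const double* gp = &g[t];
        for (int u = 0; u <= umax; ++u) acc += h[u] * gp[u];
        d[t] = acc;
      }
    }
    for (int t = 0; t < T; ++t) dX(c, t) = d[t];
  }
  return dX;
}

// Gradient w.r.t. the filter taps given dL/dY.
// [[Rcpp::export]]
NumericMatrix cc_conv1d_grad_taps(NumericMatrix dY, NumericMatrix X, IntegerVector starts, int U) {
  int C = dY.nrow(), T = dY.ncol();
  NumericMatrix dtaps(C, U);
  std::vector<int> s0, s1;
  segment_ranges(T, starts, s0, s1);
  std::vector<double> g(T), x(T);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < T; ++t) { g[t] = dY(c, t); x[t] = X(c, t); }
    for (int u = 0; u < U; ++u) {
      double acc = 0.0;
      for (size_t s = 0; s < s0.size(); ++s) {
        for (int t = s0[s] + u; t < s1[s]; ++t) acc += g[t] * x[t - u];
      }
      dtaps(c, u) = acc;
    }
  }
  return dtaps;
}

// 2D convolution over (frequency, time): causal in time, centered zero-padded
// in frequency, integrating over all input channels. A: [Cin, F, T] array,
// K: [Cout, Cin, KF, KT] array (KF odd). Segment-aware in time.
// Y[o,f,t] = sum_{ci,df,dt} K[o,ci,df,dt] * A[ci, f+df-h, t-dt]
// [[Rcpp::export]]
NumericVector cc_conv2d(NumericVector A, NumericVector K, IntegerVector starts) {
  IntegerVector da = A.attr("dim"), dk = K.attr("dim");
  int Cin = da[0], F = da[1], T = da[2];
  int Cout = dk[0], KF = dk[2], KT = dk[3];
  if (dk[1] != Cin) stop("kernel input channels mismatch");
  if (F < KF) stop("input must have at least as many frequency rows as the kernel");
  int h = (KF - 1) / 2;
  NumericVector Y(Cout * F * T);
  Y.attr("dim") = IntegerVector::create(Cout, F, T);
  std::vector<int> seg = segment_of(T, starts);
  for (int t = 0; t < T; ++t) {
    int s0 = starts[seg[t]] - 1;
    int dtmax = std::min(KT - 1, t - s0);
    for (int f = 0; f < F; ++f) {
      for (int o = 0; o < Cout; ++o) {
        double acc = 0.0;
        for (int ci = 0; ci < Cin; ++ci) {
          for (int df = 0; df < KF; ++df) {
            int fa = f + df - h;
            if (fa < 0 || fa >= F) continue;
            for (int dt = 0; dt <= dtmax; ++dt) {
              acc += K[o + Cout * (ci + Cin * (df + KF * dt))] *
                     A[ci + Cin * (fa + F * (t - dt))];
            }
          }
        }
        Y[o + Cout * (f + F * t)] = acc;
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
NumericVector cc_conv2d_grad_a(NumericVector dY, NumericVector K, IntegerVector starts,
                               int Cin, int F, int T) {
  IntegerVector dk = K.attr("dim");
  int Cout = dk[0], KF = dk[2], KT = dk[3];
  int h = (KF - 1) / 2;
  NumericVector dA(Cin * F * T);
  dA.attr("dim") = IntegerVector::create(Cin, F, T);
  std::vector<int> seg = segment_of(T, starts);
  int n = starts.size();
  for (int t = 0; t < T; ++t) {
    // A[.,.,t] feeds Y[.,.,t+dt] for dt in 0..KT-1 within the same segment
    int send = (seg[t] + 1 < n) ? (starts[seg[t] + 1] - 1) : T;
    int dtmax = std::min(KT - 1, send - 1 - t);
    for (int fa = 0; fa < F; ++fa) {
      for (int ci = 0; ci < Cin; ++ci) {
        double acc = 0.0;
        for (int df = 0; df < KF; ++df) {
          int f = fa - df + h; // output row receiving A[ci,fa,] via kernel row df
          if (f < 0 || f >= F) continue;
          for (int dt = 0; dt <= dtmax; ++dt) {
            for (int o = 0; o < Cout; ++o) {
              acc += K[o + Cout * (ci + Cin * (df + KF * dt))] *
                     dY[o + Cout * (f + F * (t + dt))];
            }
          }
        }
        dA[ci + Cin * (fa + F * t)] = acc;
      }
    }
  }
  return dA;
}

// [[Rcpp::export]]
NumericVector cc_conv2d_grad_k(NumericVector dY, NumericVector A, IntegerVector starts,
                               int Cout, int Cin, int KF, int KT) {
  IntegerVector da = A.attr("dim");
  int F = da[1], T = da[2];
  int h = (KF - 1) / 2;
  NumericVector dK(Cout * Cin * KF * KT);
  dK.attr("dim") = IntegerVector::create(Cout, Cin, KF, KT);
  std::vector<int> seg = segment_of(T, starts);
  for (int t = 0; t < T; ++t) {
    int s0 = starts[seg[t]] - 1;
    int dtmax = std::min(KT - 1, t - s0);
    for (int f = 0; f < F; ++f) {
      for (int o = 0; o < Cout; ++o) {
        double g = dY[o + Cout * (f + F * t)];
        if (g == 0.0) continue;
        for (int ci = 0; ci < Cin; ++ci) {
          for (int df = 0; df < KF; ++df) {
            int fa = f + df - h;
            if (fa < 0 || fa >= F) continue;
            for (int dt = 0; dt <= dtmax; ++dt) {
              dK[o + Cout * (ci + Cin * (df + KF * dt))] +=
                g * A[ci + Cin * (fa + F * (t - dt))];
            }
          }
        }
      }
    }
  }
  return dK;
}
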