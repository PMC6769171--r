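#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Type-7 quantile (R default) of the pairwise |x_i - x_j| distances
// (each unordered pair once), mirroring stats::quantile arithmetic so the
// C++ and R recurrence constructions agree bitwise on ties.
static double pair_dist_quantile(const double *x, int n, double p) {
  const int m = n * (n - 1) / 2;
  std::vector<double> d;
  d.reserve(m);
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      d.push_back(std::fabs(x[i] - x[j]));
  double h = (m - 1) * p;            // 0-based index
  int lo = (int)std::floor(h);
  double g = h - lo;
  std::nth_element(d.begin(), d.begin() + lo, d.end());
  double dlo = d[lo];
  if (g <= 0.0) return dlo;
  double dhi = *std::min_element(d.begin() + lo + 1, d.end());
  return (1.0 - g) * dlo + g * dhi;
}

// RMD (Eqs 3-7 evaluated on scalar series) for aligned segments x, y of
// length n: fixed-recurrence-rate thresholds, marginal and joint recurrence
// densities, log2 of the mean density ratio. Degenerate (constant) series
// give an all-recurrent matrix, matching the R reference.
static double rmd_aligned(const double *x, const double *y, int n, double rr) {
  double ex = pair_dist_quantile(x, n, rr);
  double ey = pair_dist_quantile(y, n, rr);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int px = 0, py = 0, pj = 0;
    for (int j = 0; j < n; ++j) {
      bool rx = std::fabs(x[i] - x[j]) <= ex;
      bool ry = std::fabs(y[i] - y[j]) <= ey;
      px += rx;
      py += ry;
      pj += (rx && ry);
    }
    // densities P = count/n; ratio = (pj/n) / ((px/n)*(py/n)) = pj*n/(px*py)
    acc += (double)pj * n / ((double)px * (double)py);
  }
  return std::log2(acc / n);
}

// RMD at one lag: pairs (x(t_i), y(t_i + tau)) within [0, n), overlap
// length n - |tau|. tau != 0.
static double rmd_at_lag(const double *x, const double *y, int n, int tau,
                         double rr) {
  int a = std::abs(tau);
  int m = n - a;
  if (tau > 0) return rmd_aligned(x, y + a, m, rr);
  return rmd_aligned(x + a, y, m, rr);
}

// [[Rcpp::export(name = ".rmd_profile_cpp")]]
NumericVector rmd_profile_cpp(NumericVector x, NumericVector y,
                              IntegerVector lags, double rr) {
  int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  NumericVector out(lags.size());
  for (int i = 0; i < lags.size(); ++i) {
    if (lags[i] == 0) stop("lag 0 is not evaluated");
    if (n - std::abs(lags[i]) < 10) stop("overlap shorter than 10 samples");
    out[i] = rmd_at_lag(REAL(x), REAL(y), n, lags[i], rr);
  }
  return out;
}

// Lag scan with the package's tie rule: lags visited in order of
// increasing |tau|, positive sign first; only a strictly larger RMD
// displaces the incumbent, so the smallest |tau| (and + over -) wins ties.
static void scan_best(const double *x, const double *y, int n, int taumax,
                      double rr, double *best_rmd, int *best_tau) {
  double bv = R_NegInf;
  int bt = 0;
  for (int a = 1; a <= taumax; ++a) {
    for (int s = 0; s < 2; ++s) {
      int tau = s == 0 ? a : -a;
      double v = rmd_at_lag(x, y, n, tau, rr);
      if (v > bv) { bv = v; bt = tau; }
    }
  }
  *best_rmd = bv;
  *best_tau = bt;
}

// Windowed lag-scan over K trials: X, Y are n_samples x K envelope
// matrices for one channel pair; starts are 0-based window start samples,
// wlen the window length. Returns RMD* and tau* per trial and window.
// [[Rcpp::export(name = ".rmd_scan_cpp")]]
List rmd_scan_cpp(NumericMatrix X, NumericMatrix Y, IntegerVector starts,
                  int wlen, int taumax, double rr) {
  int ns = X.nrow(), K = X.ncol(), W = starts.size();
  if (Y.nrow() != ns || Y.ncol() != K) stop("X and Y must have equal dimensions");
  if (wlen - taumax < 10)
    stop("window too short: need window length - tau_max >= 10 samples");
  for (int w = 0; w < W; ++w)
    if (starts[w] < 0 || starts[w] + wlen > ns)
      stop("window exceeds trial bounds");
  NumericMatrix rmd(K, W);
  IntegerMatrix tau(K, W);
  for (int k = 0; k < K; ++k) {
    const double *xk = &X(0, k), *yk = &Y(0, k);
    for (int w = 0; w < W; ++w) {
      double bv; int bt;
      scan_best(xk + starts[w], yk + starts[w], wlen, taumax, rr, &bv, &bt);
      rmd(k, w) = bv;
      tau(k, w) = bt;
    }
  }
  return List::create(_["rmd"] = rmd, _["tau"] = tau);
}
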