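#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Batch calibration kernels for the Monte-Carlo SPD machinery.
//
// Both kernels assume the curve's expected 14C age (mu) is non-decreasing
// in calendar age, which holds for the monotone toy curves used in
// simulation; the R-level calibrate() makes no such assumption and is the
// reference implementation. Each date's Gaussian weight is evaluated only
// where it is numerically non-zero (within nsd combined standard
// deviations of the CRA), located by binary search on mu.

static void support_range(const NumericVector& mu, double lo_mu, double hi_mu,
                          int& lo, int& hi) {
  lo = std::lower_bound(mu.begin(), mu.end(), lo_mu) - mu.begin();
  hi = std::upper_bound(mu.begin(), mu.end(), hi_mu) - mu.begin();
  if (lo > 0) --lo;                 // pad one cell for interpolation edges
  if (hi < mu.size()) ++hi;
}

// Sum of per-date normalised calibrated densities over a window of the
// curve grid. cra/err: one entry per date; mu/sigc: curve on its full 1-yr
// grid; w0/w1: 1-based inclusive window into that grid. Each date
// contributes total mass 1 (before window clipping), i.e. a singleton bin.
// [[Rcpp::export(name = ".spd_sum_c")]]
NumericVector spd_sum_c(NumericVector cra, NumericVector err,
                        NumericVector mu, NumericVector sigc,
                        int w0, int w1, double nsd = 7.0) {
  const int n = cra.size(), ng = mu.size();
  if (w0 < 1 || w1 > ng || w1 < w0) stop("window outside curve grid");
  double sc_max = 0.0;
  for (int i = 0; i < ng; ++i) sc_max = std::max(sc_max, sigc[i]);
  NumericVector out(w1 - w0 + 1);
  std::vector<double> w;
  for (int d = 0; d < n; ++d) {
    const double smax = std::sqrt(err[d] * err[d] + sc_max * sc_max);
    int lo, hi;
    support_range(mu, cra[d] - nsd * smax, cra[d] + nsd * smax, lo, hi);
    if (hi <= lo) continue;
    w.assign(hi - lo, 0.0);
    double tot = 0.0;
    for (int i = lo; i < hi; ++i) {
      const double s2 = err[d] * err[d] + sigc[i] * sigc[i];
      if (s2 <= 0.0) continue;
      const double z = cra[d] - mu[i];
      const double wi = std::exp(-0.5 * z * z / s2) / std::sqrt(s2);
      w[i - lo] = wi;
      tot += wi;
    }
    if (tot <= 0.0) continue;
    const int a = std::max(lo, w0 - 1), b = std::min(hi, w1);
    for (int i = a; i < b; ++i) out[i - (w0 - 1)] += w[i - lo] / tot;
  }
  return out;
}

// Per-date calibrated mode (cal BP) on the curve grid; ties broken toward
// the older (larger cal BP) year, matching cal_mode().
// [[Rcpp::export(name = ".cal_modes_c")]]
NumericVector cal_modes_c(NumericVector cra, NumericVector err,
                          NumericVector mu, NumericVector sigc,
                          NumericVector grid, double nsd = 7.0) {
  const int n = cra.size(), ng = mu.size();
  double sc_max = 0.0;
  for (int i = 0; i < ng; ++i) sc_max = std::max(sc_max, sigc[i]);
  NumericVector out(n);
  for (int d = 0; d < n; ++d) {
    const double smax = std::sqrt(err[d] * err[d] + sc_max * sc_max);
    int lo, hi;
    support_range(mu, cra[d] - nsd * smax, cra[d] + nsd * smax, lo, hi);
    if (hi <= lo) { out[d] = NA_REAL; continue; }
    double best = -1.0; int best_i = lo;
    for (int i = lo; i < hi; ++i) {
      const double s2 = err[d] * err[d] + sigc[i] * sigc[i];
      if (s2 <= 0.0) continue;
      const double z = cra[d] - mu[i];
      const double wi = std::exp(-0.5 * z * z / s2) / std::sqrt(s2);
      if (wi >= best) { best = wi; best_i = i; }  // >= keeps the older year
    }
    out[d] = best < 0.0 ? NA_REAL : grid[best_i];
  }
  return out;
}

// Row-wise pair of quantiles (type-7) for a dense matrix; the Monte-Carlo
// envelope needs two quantiles of every grid row of a n_grid x n_sim
// matrix, which apply()+quantile() makes needlessly slow.
// [[Rcpp::export(name = ".row_quantiles_c")]]
NumericMatrix row_quantiles_c(NumericMatrix x, double p_lo, double p_hi) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix out(n, 2);
  std::vector<double> row(m);
  auto q7 = [&](double p) {
    const double h = (m - 1) * p;
    const int lo = (int)std::floor(h);
    const int hi = std::min(lo + 1, m - 1);
    std::nth_element(row.begin(), row.begin() + lo, row.end());
    const double a = row[lo];
    const double b = *std::min_element(row.begin() + hi, row.end());
    return a + (h - lo) * (b - a);
  };
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) row[j] = x(i, j);
    out(i, 0) = q7(p_lo);
    for (int j = 0; j < m; ++j) row[j] = x(i, j);   // nth_element permutes
    out(i, 1) = q7(p_hi);
  }
  return out;
}
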