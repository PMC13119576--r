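#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Sample entropy match counts (Chebyshev distance, self-matches excluded).
// B = pairs of m-length templates within r, A = pairs of (m+1)-length templates,
// both over the first N - m template start points so every template has an
// (m+1)-length continuation.
// [[Rcpp::export]]
List cpp_sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m; // template starts 0..nt-1
  if (nt < 2) return List::create(_["A"] = 0.0, _["B"] = 0.0);
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dmax = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k] - x[j + k]);
        if (d > dmax) dmax = d;
        if (dmax > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}

static inline double embed_dist(const double* x, int i, int j, int dim, int delay) {
  double s = 0.0;
  for (int k = 0; k < dim; ++k) {
    double d = x[i + k * delay] - x[j + k * delay];
    s += d * d;
  }
  return std::sqrt(s);
}

// squared distance with early abandon once the partial sum exceeds cap2
static inline double embed_dist2_capped(const double* x, int i, int j, int dim,
                                        int delay, double cap2) {
  double s = 0.0;
  for (int k = 0; k < dim; ++k) {
    double d = x[i + k * delay] - x[j + k * delay];
    s += d * d;
    if (s > cap2) return s;
  }
  return s;
}

// Calibrate the recurrence threshold by bisection on the stored pairwise
// distance distribution (pairs with |i-j| > theiler) so the recurrence rate
// hits target_rr. Returns eps, achieved rr and the bisection trace.
// [[Rcpp::export]]
List cpp_rqa_calibrate(NumericVector x, int dim, int delay, int theiler,
                       double target_rr, double rr_tol, int max_iter) {
  const int n = x.size();
  const int ne = n - (dim - 1) * delay;
  if (ne < 2) stop("series too short for the requested embedding");
  const double* px = REAL(x);
  std::vector<float> dists;
  {
    // pairs i<j with j - i > theiler
    int64_t npairs = 0;
    for (int i = 0; i < ne; ++i) {
      int j0 = i + theiler + 1;
      if (j0 < ne) npairs += (ne - j0);
    }
    dists.reserve((size_t)npairs);
  }
  double dmax = 0.0;
  for (int i = 0; i < ne; ++i) {
    for (int j = i + theiler + 1; j < ne; ++j) {
      double d = embed_dist(px, i, j, dim, delay);
      if (d > dmax) dmax = d;
      dists.push_back((float)d);
    }
  }
  const double total = (double)dists.size();
  if (total < 1) stop("no off-Theiler pairs available");
  double lo = 0.0, hi = dmax, eps = dmax / 2.0, rr = 0.0;
  std::vector<double> tr_eps, tr_rr;
  // rr at hi is 1 (all pairs), at lo is 0: target in (0,1) is always bracketed
  for (int it = 0; it < max_iter; ++it) {
    eps = 0.5 * (lo + hi);
    int64_t cnt = 0;
    for (size_t k = 0; k < dists.size(); ++k) if (dists[k] <= eps) ++cnt;
    rr = (double)cnt / total;
    tr_eps.push_back(eps);
    tr_rr.push_back(rr);
    if (std::fabs(rr - target_rr) <= rr_tol) break;
    if (rr > target_rr) hi = eps; else lo = eps;
  }
  return List::create(_["eps"] = eps, _["rr"] = rr,
                      _["trace_eps"] = wrap(tr_eps), _["trace_rr"] = wrap(tr_rr),
                      _["n_embedded"] = ne);
}

// Recurrence measures at a fixed threshold. The recurrence set is all ordered
// pairs (i, j), i != j, with |i - j| > theiler (symmetric matrix, line of
// identity and Theiler band excluded). DET = fraction of recurrent points on
// diagonal lines of length >= lmin; LAM = same for vertical lines. Runs are
// broken by the Theiler band.
// [[Rcpp::export]]
List cpp_rqa_measures(NumericVector x, int dim, int delay, int theiler,
                      double eps, int lmin) {
  const int n = x.size();
  const int ne = n - (dim - 1) * delay;
  if (ne < 2) stop("series too short for the requested embedding");
  const double* px = REAL(x);
  int64_t n_rec = 0, n_diag = 0, n_vert = 0;
  // diagonals: offset d > theiler, upper triangle; counts doubled by symmetry
  const double eps2 = eps * eps;
  for (int d = theiler + 1; d < ne; ++d) {
    int run = 0;
    const int len = ne - d;
    for (int i = 0; i < len; ++i) {
      bool rec = embed_dist2_capped(px, i, i + d, dim, delay, eps2) <= eps2;
      if (rec) { ++n_rec; ++run; }
      if (!rec || i == len - 1) {
        if (run >= lmin) n_diag += run;
        run = 0;
      }
    }
  }
  n_rec *= 2; n_diag *= 2;
  // vertical lines: for each column j, runs over i in the included region
  for (int j = 0; j < ne; ++j) {
    int run = 0;
    for (int i = 0; i < ne; ++i) {
      bool incl = std::abs(i - j) > theiler;
      bool rec = incl &&
        (embed_dist2_capped(px, i, j, dim, delay, eps2) <= eps2);
      if (rec) ++run;
      if (!rec || i == ne - 1) {
        if (run >= lmin) n_vert += run;
        run = 0;
      }
    }
  }
  double det = (n_rec > 0) ? (double)n_diag / (double)n_rec : NA_REAL;
  double lam = (n_rec > 0) ? (double)n_vert / (double)n_rec : NA_REAL;
  int64_t denom = 0;
  for (int i = 0; i < ne; ++i) {
    int j0 = i + theiler + 1;
    if (j0 < ne) denom += (ne - j0);
  }
  double rr = (denom > 0) ? (double)(n_rec / 2) / (double)denom : NA_REAL;
  return List::create(_["rr"] = rr, _["det"] = det, _["lam"] = lam,
                      _["n_recurrent"] = (double)n_rec);
}

// False nearest neighbours fraction for one embedding dimension.
// Reference points subsampled with a fixed stride for speed; neighbours are
// searched over all embedded points with temporal exclusion |i-j| <= excl.
// [[Rcpp::export]]
double cpp_fnn_fraction(NumericVector x, int dim, int delay, int excl,
                        double rtol, double atol, double attractor_size,
                        int n_ref) {
  const int n = x.size();
  const int ne = n - dim * delay; // need component at index i + dim*delay
  if (ne < 10) stop("series too short for FNN at this dimension");
  const double* px = REAL(x);
  int stride = ne / n_ref; if (stride < 1) stride = 1;
  int64_t n_false = 0, n_tot = 0;
  for (int i = 0; i < ne; i += stride) {
    double best2 = R_PosInf; int jbest = -1;
    for (int j = 0; j < ne; ++j) {
      if (std::abs(i - j) <= excl) continue;
      double d2 = embed_dist2_capped(px, i, j, dim, delay, best2);
      if (d2 < best2) { best2 = d2; jbest = j; }
    }
    if (jbest < 0) continue;
    double best = std::sqrt(best2);
    double extra = std::fabs(px[i + dim * delay] - px[jbest + dim * delay]);
    double d1 = std::sqrt(best * best + extra * extra);
    bool is_false = false;
    // ratio test only when the neighbour distance is numerically resolvable,
    // otherwise exact recurrences make the ratio pure floating-point noise
    if (best > 1e-10 * attractor_size) {
      if (extra / best > rtol) is_false = true;
    }
    if (d1 / attractor_size > atol) is_false = true;
    ++n_tot;
    if (is_false) ++n_false;
  }
  return n_tot > 0 ? (double)n_false / (double)n_tot : NA_REAL;
}

// Sway density counts: for each sample t, the number of samples u (including
// t itself) whose planar CoP position lies within `radius` of CoP(t).
// [[Rcpp::export]]
NumericVector cpp_sway_density_counts(NumericVector ap, NumericVector ml,
                                      double radius) {
  const int n = ap.size();
  NumericVector cnt(n);
  const double r2 = radius * radius;
  for (int i = 0; i < n; ++i) cnt[i] = 1.0; // self
  for (int i = 0; i < n - 1; ++i) {
    double xi = ap[i], yi = ml[i];
    for (int j = i + 1; j < n; ++j) {
      double dx = ap[j] - xi, dy = ml[j] - yi;
      if (dx * dx + dy * dy <= r2) { cnt[i] += 1.0; cnt[j] += 1.0; }
    }
  }
  return cnt;
}

// Planar mean-square displacement for lags 1..max_lag (samples).
// [[Rcpp::export]]
NumericVector cpp_planar_msd(NumericVector ap, NumericVector ml, int max_lag) {
  const int n = ap.size();
  NumericVector msd(max_lag);
  for (int lag = 1; lag <= max_lag; ++lag) {
    double s = 0.0;
    const int m = n - lag;
    for (int i = 0; i < m; ++i) {
      double dx = ap[i + lag] - ap[i], dy = ml[i + lag] - ml[i];
      s += dx * dx + dy * dy;
    }
    msd[lag - 1] = s / (double)m;
  }
  return msd;
}
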