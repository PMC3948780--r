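#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Smoothing kernels on t = r - d, bandwidth h.
// code 0: box kernel with half-open support t in (-h, h], so that with h equal
//         to half the bin width the kernel estimator reproduces a left-closed
//         [lo, hi) histogram exactly;
// code 1: Epanechnikov, 0.75 (1 - (t/h)^2) / h on |t| < h.
static inline double kern(double t, double h, int code) {
  if (code == 0) {
    return (t > -h && t <= h) ? 0.5 / h : 0.0;
  }
  double u = t / h;
  if (u <= -1.0 || u >= 1.0) return 0.0;
  return 0.75 * (1.0 - u * u) / h;
}

// Indices of the sorted grid r touched by a pair at distance d: [lo, hi).
static inline void support_range(const NumericVector &r, double d, double h,
                                 int &lo, int &hi) {
  // generous bounds; kern() zeroes anything outside the true support
  lo = static_cast<int>(std::lower_bound(r.begin(), r.end(), d - h - 1e-12) - r.begin());
  hi = static_cast<int>(std::upper_bound(r.begin(), r.end(), d + h + 1e-12) - r.begin());
}

// S(r_k) = sum_{i != j} k_h(r_k - d_ij) e_ij for one pattern, where d_ij is the
// patch-edge distance and e_ij the translation edge-correction weight
// A / ((W - |dx|)(H - |dy|)) computed on centroid displacements (or 1).
// [[Rcpp::export]]
NumericVector cpp_pcf_sum(NumericVector x, NumericVector y, NumericVector rad,
                          double wx, double wy, NumericVector r, double h,
                          int kernel, bool translation) {
  const int n = x.size(), m = r.size();
  const double area = wx * wy;
  NumericVector out(m);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d = std::sqrt(dx * dx + dy * dy) - rad[i] - rad[j];
      double w = 1.0;
      if (translation) {
        double ax = wx - std::fabs(dx), ay = wy - std::fabs(dy);
        if (ax <= 0.0 || ay <= 0.0) continue; // pair not observable anywhere
        w = area / (ax * ay);
      }
      int lo, hi;
      support_range(r, d, h, lo, hi);
      for (int k = lo; k < hi; ++k) {
        double kv = kern(r[k] - d, h, kernel);
        if (kv > 0.0) out[k] += 2.0 * w * kv; // both ordered pairs
      }
    }
  }
  return out;
}

// Cross-pattern version: S(r_k) = sum_{i in a, j in b} k_h(r_k - d_ij) e_ij,
// counting each ordered (a, b) pair once (normalisation uses Na * Nb).
// [[Rcpp::export]]
NumericVector cpp_pccf_sum(NumericVector x1, NumericVector y1, NumericVector r1,
                           NumericVector x2, NumericVector y2, NumericVector r2,
                           double wx, double wy, NumericVector r, double h,
                           int kernel, bool translation) {
  const int n1 = x1.size(), n2 = x2.size(), m = r.size();
  const double area = wx * wy;
  NumericVector out(m);
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n2; ++j) {
      double dx = x1[i] - x2[j], dy = y1[i] - y2[j];
      double d = std::sqrt(dx * dx + dy * dy) - r1[i] - r2[j];
      double w = 1.0;
      if (translation) {
        double ax = wx - std::fabs(dx), ay = wy - std::fabs(dy);
        if (ax <= 0.0 || ay <= 0.0) continue;
        w = area / (ax * ay);
      }
      int lo, hi;
      support_range(r, d, h, lo, hi);
      for (int k = lo; k < hi; ++k) {
        double kv = kern(r[k] - d, h, kernel);
        if (kv > 0.0) out[k] += w * kv;
      }
    }
  }
  return out;
}

// Per-patch minimum edge distance to any other patch (Inf when alone).
// [[Rcpp::export]]
NumericVector cpp_min_edge_each(NumericVector x, NumericVector y, NumericVector rad) {
  const int n = x.size();
  NumericVector out(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d = std::sqrt(dx * dx + dy * dy) - rad[i] - rad[j];
      if (d < out[i]) out[i] = d;
      if (d < out[j]) out[j] = d;
    }
  }
  return out;
}

// Minimum pairwise edge distance of one pattern (Inf when n < 2).
// [[Rcpp::export]]
double cpp_min_edge_pair(NumericVector x, NumericVector y, NumericVector rad) {
  const int n = x.size();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d = std::sqrt(dx * dx + dy * dy) - rad[i] - rad[j];
      if (d < best) best = d;
    }
  return best;
}

// For each patch in set 1, minimum edge distance to set 2.
// [[Rcpp::export]]
NumericVector cpp_cross_min_edge(NumericVector x1, NumericVector y1, NumericVector r1,
                                 NumericVector x2, NumericVector y2, NumericVector r2) {
  const int n1 = x1.size(), n2 = x2.size();
  NumericVector out(n1, R_PosInf);
  for (int i = 0; i < n1; ++i)
    for (int j = 0; j < n2; ++j) {
      double dx = x1[i] - x2[j], dy = y1[i] - y2[j];
      double d = std::sqrt(dx * dx + dy * dy) - r1[i] - r2[j];
      if (d < out[i]) out[i] = d;
    }
  return out;
}

// Sum of isotropic bivariate Gaussian kernels (each integrating to 1 over the
// plane, no boundary renormalisation) evaluated on a grid; separable form.
// Returns a matrix with rows indexing gx and columns indexing gy.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_kde(NumericVector cx, NumericVector cy,
                            NumericVector gx, NumericVector gy, double sd) {
  const int n = cx.size(), nx = gx.size(), ny = gy.size();
  NumericMatrix out(nx, ny);
  const double norm = 1.0 / (2.0 * M_PI * sd * sd);
  std::vector<double> ex(nx), ey(ny);
  for (int c = 0; c < n; ++c) {
    for (int i = 0; i < nx; ++i) {
      double t = (gx[i] - cx[c]) / sd;
      ex[i] = std::exp(-0.5 * t * t);
    }
    for (int j = 0; j < ny; ++j) {
      double t = (gy[j] - cy[c]) / sd;
      ey[j] = std::exp(-0.5 * t * t);
    }
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        out(i, j) += norm * ex[i] * ey[j];
  }
  return out;
}

static inline bool overlaps(double px, double py, double pr,
                            const NumericVector &x, const NumericVector &y,
                            const NumericVector &r, int upto) {
  for (int i = 0; i < upto; ++i) {
    double dx = px - x[i], dy = py - y[i];
    double lim = pr + r[i];
    if (dx * dx + dy * dy < lim * lim) return true;
  }
  return false;
}

// Sequential random placement of discs with radii `rad` (caller sorts them,
// largest first) inside [x0, x1] x [y0, y1], whole-disc containment, no
// overlap with the fixed discs (fx, fy, fr) nor with previously placed ones.
// `weights` empty -> uniform proposals; otherwise `weights` holds cell masses
// of an nx-by-ny lattice (row-major in x) with cell sizes stepx, stepy, and
// proposals are cell draws jittered uniformly within the cell.
// Returns an n x 2 matrix of centroids, or a 1x1 matrix carrying the 1-based
// index of the disc whose placement failed (negative value).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix cpp_place_discs(NumericVector rad, double x0, double y0,
                              double x1, double y1,
                              NumericVector fx, NumericVector fy, NumericVector fr,
                              int max_attempts, NumericVector weights,
                              int nx, int ny, double stepx, double stepy) {
  const int n = rad.size();
  NumericVector px(n), py(n);
  const bool weighted = weights.size() > 0;
  std::vector<double> cum;
  double total = 0.0;
  if (weighted) {
    cum.resize(weights.size());
    for (int i = 0; i < weights.size(); ++i) {
      total += weights[i];
      cum[i] = total;
    }
  }
  for (int i = 0; i < n; ++i) {
    double r = rad[i];
    bool ok = false;
    for (int att = 0; att < max_attempts; ++att) {
      double cx, cy;
      if (weighted) {
        double u = unif_rand() * total;
        int cell = static_cast<int>(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
        if (cell >= nx * ny) cell = nx * ny - 1;
        int ix = cell % nx, iy = cell / nx;
        cx = x0 + (ix + unif_rand()) * stepx;
        cy = y0 + (iy + unif_rand()) * stepy;
        if (cx - r < x0 || cx + r > x1 || cy - r < y0 || cy + r > y1) continue;
      } else {
        if (x1 - x0 < 2.0 * r || y1 - y0 < 2.0 * r) break; // cannot fit
        cx = x0 + r + unif_rand() * (x1 - x0 - 2.0 * r);
        cy = y0 + r + unif_rand() * (y1 - y0 - 2.0 * r);
      }
      if (overlaps(cx, cy, r, fx, fy, fr, fx.size())) continue;
      if (overlaps(cx, cy, r, px, py, rad, i)) continue;
      px[i] = cx;
      py[i] = cy;
      ok = true;
      break;
    }
    if (!ok) {
      NumericMatrix fail(1, 1);
      fail(0, 0) = -(i + 1);
      return fail;
    }
  }
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = px[i];
    out(i, 1) = py[i];
  }
  return out;
}
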