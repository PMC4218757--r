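#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Antiderivative of sqrt(r^2 - u^2) on [-r, r].
static inline double int_s(double u, double r) {
  double r2 = r * r;
  double s2 = r2 - u * u;
  double s = s2 > 0.0 ? std::sqrt(s2) : 0.0;
  return 0.5 * (u * s + r2 * std::asin(u / r));
}

// Area of {u^2 + v^2 <= r^2} intersected with the quarter-plane
// {u <= x, v <= y}, disc centred at the origin.  Closed form via
// integration of the in-disc chord length; exact up to floating point.
static double quad_area(double x, double y, double r) {
  if (r <= 0.0) return 0.0;
  if (x <= -r || y <= -r) return 0.0;
  double xc = x < r ? x : r;
  if (y >= r) return 2.0 * (int_s(xc, r) - int_s(-r, r));
  double t = std::sqrt(r * r - y * y);
  if (y >= 0.0) {
    // chord height is 2*s(u) for |u| > t, y + s(u) for |u| <= t
    double res = 0.0;
    if (xc <= -t) return 2.0 * (int_s(xc, r) - int_s(-r, r));
    res += 2.0 * (int_s(-t, r) - int_s(-r, r));
    double b = xc < t ? xc : t;
    res += y * (b + t) + (int_s(b, r) - int_s(-t, r));
    if (xc > t) res += 2.0 * (int_s(xc, r) - int_s(t, r));
    return res;
  }
  // y < 0: only u in [-t, t] contributes, height y + s(u)
  double hi = xc < t ? xc : t;
  if (hi <= -t) return 0.0;
  return y * (hi + t) + (int_s(hi, r) - int_s(-t, r));
}

// Disc of radius r centred at (cx, cy) intersected with the axis-aligned
// rectangle [x0,x1] x [y0,y1]: inclusion-exclusion over the four corners.
static inline double disc_rect(double cx, double cy, double r,
                               double x0, double y0, double x1, double y1) {
  if (r <= 0.0) return 0.0;
  double a = quad_area(x1 - cx, y1 - cy, r)
           - quad_area(x0 - cx, y1 - cy, r)
           - quad_area(x1 - cx, y0 - cy, r)
           + quad_area(x0 - cx, y0 - cy, r);
  return a > 0.0 ? a : 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_disc_rect_area(NumericVector cx, NumericVector cy,
                                 NumericVector r,
                                 double x0, double y0, double x1, double y1) {
  R_xlen_t n = cx.size();
  if (cy.size() != n || r.size() != n)
    stop("cx, cy and r must have equal length");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = disc_rect(cx[i], cy[i], r[i], x0, y0, x1, y1);
  return out;
}

// Per-focal-point in-window annulus areas for a uniform ring ladder:
// returns an n_focal x n_rings matrix of areas of
// [k*w, (k+1)*w) annuli clipped to the window.
// [[Rcpp::export]]
NumericMatrix cpp_ladder_areas(NumericVector fx, NumericVector fy,
                               double w, int n_rings,
                               double x0, double y0, double x1, double y1) {
  R_xlen_t n = fx.size();
  NumericMatrix out(n, n_rings);
  for (R_xlen_t i = 0; i < n; ++i) {
    double prev = 0.0;
    for (int k = 0; k < n_rings; ++k) {
      double cur = disc_rect(fx[i], fy[i], (k + 1) * w, x0, y0, x1, y1);
      out(i, k) = cur - prev;
      prev = cur;
    }
  }
  return out;
}

// Pairwise neighbour counts per ring of a uniform ladder (half-open
// rings [k*w, (k+1)*w)).  exclude_self drops pairs with equal index and
// is only meaningful when focal and neighbour are the same point set in
// the same order.
// [[Rcpp::export]]
IntegerVector cpp_ring_counts(NumericVector fx, NumericVector fy,
                              NumericVector nx, NumericVector ny,
                              double w, int n_rings, bool exclude_self) {
  R_xlen_t nf = fx.size(), nn = nx.size();
  IntegerVector out(n_rings);
  double rmax = w * n_rings;
  double rmax2 = rmax * rmax;
  for (R_xlen_t i = 0; i < nf; ++i) {
    double xi = fx[i], yi = fy[i];
    for (R_xlen_t j = 0; j < nn; ++j) {
      if (exclude_self && i == j) continue;
      double dx = nx[j] - xi, dy = ny[j] - yi;
      double d2 = dx * dx + dy * dy;
      if (d2 >= rmax2) continue;
      int k = (int)(std::sqrt(d2) / w);
      if (k >= n_rings) continue; // guard against fp rounding at rmax
      ++out[k];
    }
  }
  return out;
}

// Per-focal version: n_focal x n_rings matrix of neighbour counts.
// [[Rcpp::export]]
IntegerMatrix cpp_ring_counts_by_focal(NumericVector fx, NumericVector fy,
                                       NumericVector nx, NumericVector ny,
                                       double w, int n_rings,
                                       bool exclude_self) {
  R_xlen_t nf = fx.size(), nn = nx.size();
  IntegerMatrix out(nf, n_rings);
  double rmax = w * n_rings;
  double rmax2 = rmax * rmax;
  for (R_xlen_t i = 0; i < nf; ++i) {
    double xi = fx[i], yi = fy[i];
    for (R_xlen_t j = 0; j < nn; ++j) {
      if (exclude_self && i == j) continue;
      double dx = nx[j] - xi, dy = ny[j] - yi;
      double d2 = dx * dx + dy * dy;
      if (d2 >= rmax2) continue;
      int k = (int)(std::sqrt(d2) / w);
      if (k >= n_rings) continue;
      ++out(i, k);
    }
  }
  return out;
}
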