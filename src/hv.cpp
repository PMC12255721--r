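#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Internal helpers for 2-D hypervolume geometry under the maximization
// convention. Fronts are reduced to strictly non-dominated, de-duplicated
// staircases before any area computation; all points are assumed >= ref
// componentwise (validated on the R side).

struct Pt { double x, y; };

// Reduce an arbitrary 2-D point set to its non-dominated staircase,
// sorted by x ascending / y descending. Duplicates collapse to one.
static std::vector<Pt> staircase(const std::vector<Pt>& pts) {
  std::vector<Pt> s(pts);
  std::sort(s.begin(), s.end(), [](const Pt& a, const Pt& b) {
    if (a.x != b.x) return a.x > b.x;   // x descending
    return a.y > b.y;                   // then y descending
  });
  std::vector<Pt> out;
  double best_y = -std::numeric_limits<double>::infinity();
  for (const Pt& p : s) {
    if (p.y > best_y) {                 // strictly better y than anything with larger x
      out.push_back(p);
      best_y = p.y;
    }
  }
  std::reverse(out.begin(), out.end()); // x ascending, y descending
  return out;
}

// Exact dominated area of a staircase (x ascending, y descending) w.r.t. ref:
// one rectangle per front point, width to its left neighbour (or ref).
static double stair_area(const std::vector<Pt>& st, double rx, double ry) {
  double acc = 0.0;
  for (int i = (int)st.size() - 1; i >= 0; --i) {
    double x_lo = (i == 0) ? rx : st[(size_t)i - 1].x;
    if (x_lo < rx) x_lo = rx;
    acc += (st[(size_t)i].x - x_lo) * (st[(size_t)i].y - ry);
  }
  return acc;
}

// Hypervolume improvement of point p over staircase st (may be empty).
// O(k): integrate max(0, p.y - stair(a)) over a in [rx, p.x].
static double stair_hvi(const Pt& p, const std::vector<Pt>& st,
                        double rx, double ry) {
  if (p.x <= rx || p.y <= ry) return 0.0;
  double hvi = 0.0;
  // segment boundaries along x: rx, x_1, ..., x_k; stair height on
  // (x_{i-1}, x_i] is y_i (y decreasing); beyond x_k height is ry.
  double lo = rx;
  for (const Pt& s : st) {
    double hi = std::min(p.x, s.x);
    if (hi > lo && p.y > s.y) hvi += (hi - lo) * (p.y - s.y);
    lo = s.x;
    if (lo >= p.x) break;
  }
  if (p.x > lo) hvi += (p.x - lo) * (p.y - ry);  // beyond the staircase
  return hvi;
}

static std::vector<Pt> as_pts(const NumericMatrix& Y) {
  std::vector<Pt> v(Y.nrow());
  for (int i = 0; i < Y.nrow(); ++i) v[(size_t)i] = Pt{Y(i, 0), Y(i, 1)};
  return v;
}

// Clamp points to the reference: Monte-Carlo samples may fall below it, and
// only the part of a box above the reference carries volume.
static std::vector<Pt> as_pts_clamped(const NumericMatrix& Y,
                                      double rx, double ry) {
  std::vector<Pt> v(Y.nrow());
  for (int i = 0; i < Y.nrow(); ++i)
    v[(size_t)i] = Pt{std::max(Y(i, 0), rx), std::max(Y(i, 1), ry)};
  return v;
}

// [[Rcpp::export]]
double cpp_hv2d(NumericMatrix Y, NumericVector ref) {
  if (Y.nrow() == 0) return 0.0;
  std::vector<Pt> st = staircase(as_pts(Y));
  return stair_area(st, ref[0], ref[1]);
}

// [[Rcpp::export]]
NumericVector cpp_hvi2d_many(NumericMatrix cand, NumericMatrix frontY,
                             NumericVector ref) {
  std::vector<Pt> st = staircase(as_pts_clamped(frontY, ref[0], ref[1]));
  NumericVector out(cand.nrow());
  for (int i = 0; i < cand.nrow(); ++i)
    out[i] = stair_hvi(Pt{std::max(cand(i, 0), ref[0]),
                          std::max(cand(i, 1), ref[1])},
                       st, ref[0], ref[1]);
  return out;
}

// Mean HVI over Monte-Carlo samples: cand1/cand2 are S x n matrices of
// sampled objective values (sample j, candidate i); fronts is a list of S
// (k_j x 2) matrices, the per-sample non-dominated baselines.
// [[Rcpp::export]]
NumericVector cpp_mean_hvi(NumericMatrix cand1, NumericMatrix cand2,
                           List fronts, NumericVector ref) {
  int S = cand1.nrow(), n = cand1.ncol();
  NumericVector out(n);
  for (int j = 0; j < S; ++j) {
    NumericMatrix fj = fronts[j];
    std::vector<Pt> st = staircase(as_pts_clamped(fj, ref[0], ref[1]));
    for (int i = 0; i < n; ++i)
      out[i] += stair_hvi(Pt{std::max(cand1(j, i), ref[0]),
                             std::max(cand2(j, i), ref[1])},
                          st, ref[0], ref[1]);
  }
  for (int i = 0; i < n; ++i) out[i] /= (double)S;
  return out;
}

// Non-dominated mask under maximization, any dimension, O(n^2).
// Duplicated front points are all kept (mutual weak dominance is not
// counted as dominance).
// [[Rcpp::export]]
LogicalVector cpp_pareto_mask(NumericMatrix Y) {
  int n = Y.nrow(), d = Y.ncol();
  LogicalVector keep(n, true);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      bool geq = true, gt = false;
      for (int k = 0; k < d; ++k) {
        double a = Y(j, k), b = Y(i, k);
        if (a < b) { geq = false; break; }
        if (a > b) gt = true;
      }
      if (geq && gt) { keep[i] = false; break; }
    }
  }
  return keep;
}
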