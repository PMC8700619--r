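#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pairwise distance matrix between the rows of two point sets sharing a
// dimension. Euclidean or maximum (Chebyshev) norm.
// [[Rcpp::export]]
NumericMatrix cpp_cross_dist(NumericMatrix a, NumericMatrix b, bool max_norm) {
  const int n1 = a.nrow(), n2 = b.nrow(), m = a.ncol();
  if (b.ncol() != m) stop("point sets differ in dimension");
  NumericMatrix d(n1, n2);
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      double acc = 0.0;
      if (max_norm) {
        for (int k = 0; k < m; ++k) {
          double dk = std::fabs(a(i, k) - b(j, k));
          if (dk > acc) acc = dk;
        }
      } else {
        for (int k = 0; k < m; ++k) {
          double dk = a(i, k) - b(j, k);
          acc += dk * dk;
        }
        acc = std::sqrt(acc);
      }
      d(i, j) = acc;
    }
  }
  return d;
}

// Lengths of maximal recurrent runs (>= lmin) along every diagonal of a
// rectangular matrix. A cell is recurrent iff x <= eps (le = true, distance
// matrices) or x >= eps (le = false, binary matrices with eps = 0.5).
// [[Rcpp::export]]
IntegerVector cpp_diag_runs(NumericMatrix x, double eps, int lmin, bool le) {
  const int n1 = x.nrow(), n2 = x.ncol();
  std::vector<int> runs;
  for (int off = -(n1 - 1); off <= n2 - 1; ++off) {
    int i = off < 0 ? -off : 0;
    int j = off < 0 ? 0 : off;
    int len = 0;
    for (; i < n1 && j < n2; ++i, ++j) {
      bool rec = le ? (x(i, j) <= eps) : (x(i, j) >= eps);
      if (rec) {
        ++len;
      } else {
        if (len >= lmin) runs.push_back(len);
        len = 0;
      }
    }
    if (len >= lmin) runs.push_back(len);
  }
  return wrap(runs);
}

// Exact order-statistic calibration on the raw distance multiset. RR(eps)
// jumps at the unique distances with achievable values count/M; the
// candidate unique values bracketing the target quantile are found with
// nth_element (O(M)), and the smallest distance with the closest achievable
// RR wins. Requires at least two distinct values.
static void calibrate_select(std::vector<double> &d, double target,
                             double *eps_out, double *rr_out) {
  const R_xlen_t mtot = static_cast<R_xlen_t>(d.size());
  double lo = d[0], hi = d[0];
  for (double v : d) { if (v < lo) lo = v; if (v > hi) hi = v; }
  if (lo == hi)
    stop("degenerate input: all pairwise distances are equal");

  R_xlen_t kt = static_cast<R_xlen_t>(std::floor(target * mtot + 0.5));
  if (kt < 1) kt = 1;
  if (kt > mtot) kt = mtot;
  std::nth_element(d.begin(), d.begin() + (kt - 1), d.end());
  const double v1 = d[kt - 1];

  // counts and flanking unique values around v1
  R_xlen_t c_lt = 0, c_le = 0;
  double u0 = lo, u2 = hi;
  bool has_u0 = false, has_u2 = false;
  for (double v : d) {
    if (v < v1) {
      ++c_lt;
      if (!has_u0 || v > u0) { u0 = v; has_u0 = true; }
    }
    if (v <= v1) ++c_le;
    if (v > v1 && (!has_u2 || v < u2)) { u2 = v; has_u2 = true; }
  }

  double best_eps = v1, best_rr = static_cast<double>(c_le) / mtot;
  double best_gap = std::fabs(best_rr - target);
  if (has_u0) {
    const double rr0 = static_cast<double>(c_lt) / mtot;
    const double gap0 = std::fabs(rr0 - target);
    if (gap0 < best_gap || (gap0 == best_gap && u0 < best_eps)) {
      best_eps = u0; best_rr = rr0; best_gap = gap0;
    }
  }
  if (has_u2) {
    R_xlen_t c2 = 0;
    for (double v : d) if (v <= u2) ++c2;
    const double rr2 = static_cast<double>(c2) / mtot;
    const double gap2 = std::fabs(rr2 - target);
    if (gap2 < best_gap) { best_eps = u2; best_rr = rr2; }
  }
  *eps_out = best_eps;
  *rr_out = best_rr;
}

// [[Rcpp::export]]
List cpp_calibrate(NumericVector d, double target) {
  std::vector<double> s(d.begin(), d.end());
  double eps, rr;
  calibrate_select(s, target, &eps, &rr);
  return List::create(_["epsilon"] = eps, _["achieved_rr"] = rr);
}

// Kennel false-nearest-neighbour fractions for m = 1..mmax at delay tau.
// The first n - m*tau points are used at each m so that the (m+1)-th
// coordinate exists for every point and its neighbour.
// [[Rcpp::export]]
NumericVector cpp_fnn(NumericVector x, int tau, int mmax, double rtol,
                      double atol) {
  const int n = x.size();
  double mu = 0.0, ss = 0.0;
  for (int i = 0; i < n; ++i) mu += x[i];
  mu /= n;
  for (int i = 0; i < n; ++i) ss += (x[i] - mu) * (x[i] - mu);
  const double sdx = std::sqrt(ss / (n - 1));
  if (sdx <= 0.0) stop("degenerate input: series has zero variance");

  NumericVector frac(mmax);
  for (int m = 1; m <= mmax; ++m) {
    const int np = n - m * tau;
    if (np < 2) stop("series too short for requested embedding dimension");
    int nfalse = 0;
    for (int i = 0; i < np; ++i) {
      double best = R_PosInf;
      int jbest = -1;
      for (int j = 0; j < np; ++j) {
        if (j == i) continue;
        double d2 = 0.0;
        for (int k = 0; k < m; ++k) {
          double dk = x[i + k * tau] - x[j + k * tau];
          d2 += dk * dk;
          if (d2 >= best) break;
        }
        if (d2 < best) { best = d2; jbest = j; }
      }
      const double rm = std::sqrt(best);
      const double extra = std::fabs(x[i + m * tau] - x[jbest + m * tau]);
      // ratio criterion is undefined for exactly coincident neighbours
      // (periodic revisits); the absolute criterion alone governs there
      bool isfalse = (rm > 0.0) && (extra / rm > rtol);
      if (!isfalse && std::sqrt(rm * rm + extra * extra) / sdx > atol)
        isfalse = true;
      if (isfalse) ++nfalse;
    }
    frac[m - 1] = static_cast<double>(nfalse) / np;
  }
  return frac;
}

// Fused per-pair CRQA: one cross-distance matrix serves the diameter-rule
// recurrence rate and the fixed-RR diagonal-line entropy. The joint
// phase-space diameter also scans the two within-set halves without
// materializing their distance matrices.
// [[Rcpp::export]]
List cpp_crqa_full(NumericMatrix a, NumericMatrix b, double diam_frac,
                   double target_rr, int lmin, bool max_norm) {
  const int n1 = a.nrow(), n2 = b.nrow(), m = a.ncol();
  if (b.ncol() != m) stop("point sets differ in dimension");

  NumericMatrix d(n1, n2);
  double dmax = 0.0;
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      double acc = 0.0;
      if (max_norm) {
        for (int k = 0; k < m; ++k) {
          double dk = std::fabs(a(i, k) - b(j, k));
          if (dk > acc) acc = dk;
        }
      } else {
        for (int k = 0; k < m; ++k) {
          double dk = a(i, k) - b(j, k);
          acc += dk * dk;
        }
        acc = std::sqrt(acc);
      }
      d(i, j) = acc;
      if (acc > dmax) dmax = acc;
    }
  }
  // within-set maxima (upper triangles only)
  for (int rep = 0; rep < 2; ++rep) {
    const NumericMatrix &p = rep == 0 ? a : b;
    const int np = p.nrow();
    for (int i = 0; i < np - 1; ++i) {
      for (int j = i + 1; j < np; ++j) {
        double acc = 0.0;
        if (max_norm) {
          for (int k = 0; k < m; ++k) {
            double dk = std::fabs(p(i, k) - p(j, k));
            if (dk > acc) acc = dk;
          }
          if (acc > dmax) dmax = acc;
        } else {
          for (int k = 0; k < m; ++k) {
            double dk = p(i, k) - p(j, k);
            acc += dk * dk;
          }
          if (acc > dmax * dmax) dmax = std::sqrt(acc);
        }
      }
    }
  }
  if (dmax <= 0.0) stop("degenerate input: zero phase-space diameter");

  const double eps_rr = diam_frac * dmax;
  R_xlen_t nrec = 0;
  const R_xlen_t mtot = static_cast<R_xlen_t>(n1) * n2;
  for (R_xlen_t t = 0; t < mtot; ++t) if (d[t] <= eps_rr) ++nrec;
  const double rr = static_cast<double>(nrec) / mtot;

  std::vector<double> dv(d.begin(), d.end());
  double eps_ent, achieved;
  calibrate_select(dv, target_rr, &eps_ent, &achieved);

  IntegerVector runs = cpp_diag_runs(d, eps_ent, lmin, true);

  return List::create(_["rr"] = rr, _["epsilon_rr"] = eps_rr,
                      _["epsilon_ent"] = eps_ent,
                      _["achieved_rr"] = achieved,
                      _["runs"] = runs, _["diameter"] = dmax);
}
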