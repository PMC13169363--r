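// Hartigan dip statistic, computed exactly from its definition:
//   dip(F_n) = min over unimodal CDFs G of sup_x |F_n(x) - G(x)|.
//
// A unimodal CDF is convex to the left of its mode and concave to the right
// (an atom at the mode is allowed). For a candidate sup-distance t the
// empirical CDF induces per-point value bands; a unimodal G within t of F_n
// exists iff, for some placement of the mode (inside a gap between data
// points, or as an atom at a data point), a convex function fits the bands on
// the left and a concave one fits them on the right. Convex-band feasibility
// reduces to "the greatest convex minorant of the upper bounds dominates the
// lower bounds", checkable with one monotone-chain hull pass. Feasibility is
// monotone both in t and in the prefix/suffix length, so the dip is found by
// bisection on t with binary searches over the split position.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct DipSolver {
  std::vector<double> x, l, u;   // distinct positions, CDF below / through
  std::vector<int> hull;         // workspace
  int m;
  double t;                      // current half-bandwidth

  void set_data(const double* xs, int n) {
    x.clear(); l.clear(); u.clear();
    int i = 0;
    while (i < n) {
      int j = i;
      while (j < n && xs[j] == xs[i]) j++;
      x.push_back(xs[i]);
      l.push_back((double)i / n);
      u.push_back((double)j / n);
      i = j;
    }
    m = (int)x.size();
    hull.resize(m + 1);
  }

  // interior bands, clamped to the CDF range
  inline double blo(int i) const { double v = u[i] - t; return v < 0.0 ? 0.0 : v; }
  inline double bhi(int i) const { double v = l[i] + t; return v > 1.0 ? 1.0 : v; }
  // virtual-node bands for an atom at point i (left side sees the lower CDF
  // value, right side the upper)
  inline double vlo_left(int i) const { double v = l[i] - t; return v < 0.0 ? 0.0 : v; }
  inline double vhi_left(int i) const { double v = l[i] + t; return v > 1.0 ? 1.0 : v; }
  inline double vlo_right(int i) const { double v = u[i] - t; return v < 0.0 ? 0.0 : v; }
  inline double vhi_right(int i) const { double v = u[i] + t; return v > 1.0 ? 1.0 : v; }

  // convex feasibility of nodes 0..cnt-1 where node k has position px(k),
  // upper bound phi(k), lower bound plo(k); positions strictly increasing.
  template <class PX, class PLO, class PHI>
  bool convex_feasible(int cnt, PX px, PLO plo, PHI phi) {
    const double eps = 1e-12;
    for (int i = 0; i < cnt; i++) if (plo(i) > phi(i) + eps) return false;
    if (cnt <= 2) return true;
    int hs = 0;
    for (int i = 0; i < cnt; i++) {
      while (hs >= 2) {
        int b = hull[hs - 1], a = hull[hs - 2];
        double cr = (px(b) - px(a)) * (phi(i) - phi(a)) -
                    (phi(b) - phi(a)) * (px(i) - px(a));
        if (cr <= 0) hs--; else break;
      }
      hull[hs++] = i;
    }
    int seg = 0;
    for (int i = 0; i < cnt; i++) {
      while (seg + 1 < hs && px(hull[seg + 1]) <= px(i)) seg++;
      double val;
      if (seg + 1 >= hs) val = phi(hull[seg]);
      else {
        int a = hull[seg], b = hull[seg + 1];
        val = phi(a) + (phi(b) - phi(a)) * (px(i) - px(a)) / (px(b) - px(a));
      }
      if (val < plo(i) - eps) return false;
    }
    return true;
  }

  // prefix 0..s-1 with interior bands; atom => plus virtual node at index s
  bool left_feasible(int s, bool atom) {
    int cnt = s + (atom ? 1 : 0);
    auto px = [&](int k) { return x[k]; };
    auto plo = [&](int k) { return k < s ? blo(k) : vlo_left(s); };
    auto phi = [&](int k) { return k < s ? bhi(k) : vhi_left(s); };
    return convex_feasible(cnt, px, plo, phi);
  }

  // suffix s..m-1 with interior bands; atom => plus virtual node at s-1.
  // Mirrored (negate positions and values) so concave becomes convex.
  bool right_feasible(int s, bool atom) {
    int base = m - s;                 // mirrored indices 0..base-1 are m-1..s
    int cnt = base + (atom ? 1 : 0);
    auto px = [&](int k) { return k < base ? -x[m - 1 - k] : -x[s - 1]; };
    auto plo = [&](int k) { return k < base ? -bhi(m - 1 - k) : -vhi_right(s - 1); };
    auto phi = [&](int k) { return k < base ? -blo(m - 1 - k) : -vlo_right(s - 1); };
    return convex_feasible(cnt, px, plo, phi);
  }

  bool feasible(double tt) {
    t = tt;
    // interval modes: prefix length s on the left (s = 0..m); prefix
    // feasibility is monotone decreasing in s, suffix increasing
    int smaxL = 0;
    if (left_feasible(1, false)) {
      int lo = 1, hi = m;
      while (lo < hi) {
        int mid = (lo + hi + 1) / 2;
        if (left_feasible(mid, false)) lo = mid; else hi = mid - 1;
      }
      smaxL = lo;
    }
    int sminR = m;
    if (right_feasible(m - 1, false)) {
      int lo = 0, hi = m - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (right_feasible(mid, false)) hi = mid; else lo = mid + 1;
      }
      sminR = lo;
    }
    if (sminR <= smaxL) return true;
    // atom-at-point modes: same monotone structure
    int jmaxL = -1;
    if (left_feasible(0, true)) {
      int lo = 0, hi = m - 1;
      while (lo < hi) {
        int mid = (lo + hi + 1) / 2;
        if (left_feasible(mid, true)) lo = mid; else hi = mid - 1;
      }
      jmaxL = lo;
    }
    if (jmaxL < 0) return false;
    int jminR = m;
    if (right_feasible(m, true)) {
      int lo = 0, hi = m - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (right_feasible(mid + 1, true)) hi = mid; else lo = mid + 1;
      }
      jminR = lo;
    }
    return jminR <= jmaxL;
  }

  double dip() {
    if (m <= 1) return 0.0;
    double tlo = 0.0, thi = 0.2500000001;
    for (int it = 0; it < 36; it++) {
      double mid = 0.5 * (tlo + thi);
      if (feasible(mid)) thi = mid; else tlo = mid;
    }
    return 0.5 * (tlo + thi);
  }
};

}  // namespace

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector xs) {
  int n = xs.size();
  if (n < 2) return 0.0;
  DipSolver solver;
  solver.set_data(REAL(xs), n);
  return solver.dip();
}

// dip of each column of a matrix of (unsorted) samples; used for the
// bootstrap null table
// [[Rcpp::export]]
NumericVector dip_boot_cpp(NumericMatrix samples) {
  int n = samples.nrow(), nb = samples.ncol();
  NumericVector out(nb);
  DipSolver solver;
  std::vector<double> buf(n);
  for (int b = 0; b < nb; b++) {
    for (int i = 0; i < n; i++) buf[i] = samples(i, b);
    std::sort(buf.begin(), buf.end());
    solver.set_data(buf.data(), n);
    out[b] = solver.dip();
  }
  return out;
}
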