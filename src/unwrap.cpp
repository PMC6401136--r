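#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double TWOPI = 2.0 * M_PI;

static inline double wrap_pi(double x) {
  // principal value in [-pi, pi)
  return x - TWOPI * std::floor((x + M_PI) / TWOPI);
}

// Reliability-ordered 2D phase unwrapping (second-difference reliability,
// edges sorted most-reliable first, union-find with per-group 2*pi offsets).
// Total on any finite input; border pixels get worst-case reliability.
// [[Rcpp::export(name = ".cpp_unwrap")]]
NumericMatrix cpp_unwrap(NumericMatrix wrapped) {
  const int nr = wrapped.nrow(), nc = wrapped.ncol();
  const int n = nr * nc;
  std::vector<double> val(n);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) val[i + j * nr] = wrapped(i, j);

  // pixel reliability: sum of squared wrapped second differences (H, V, two
  // diagonals); smaller = more reliable
  std::vector<double> rel(n, std::numeric_limits<double>::max());
  if (nr > 2 && nc > 2) {
    for (int j = 1; j < nc - 1; ++j) {
      for (int i = 1; i < nr - 1; ++i) {
        const int k = i + j * nr;
        double H  = wrap_pi(val[k - nr] - val[k]) - wrap_pi(val[k] - val[k + nr]);
        double V  = wrap_pi(val[k - 1]  - val[k]) - wrap_pi(val[k] - val[k + 1]);
        double D1 = wrap_pi(val[k - nr - 1] - val[k]) - wrap_pi(val[k] - val[k + nr + 1]);
        double D2 = wrap_pi(val[k - nr + 1] - val[k]) - wrap_pi(val[k] - val[k + nr - 1]);
        rel[k] = H * H + V * V + D1 * D1 + D2 * D2;
      }
    }
  }

  struct Edge { double r; int p, q; };
  std::vector<Edge> edges;
  edges.reserve(2 * (size_t)n);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const int k = i + j * nr;
      double rk = (rel[k] == std::numeric_limits<double>::max()) ? 1e30 : rel[k];
      if (i + 1 < nr) {
        double rq = (rel[k + 1] == std::numeric_limits<double>::max()) ? 1e30 : rel[k + 1];
        edges.push_back({rk + rq, k, k + 1});
      }
      if (j + 1 < nc) {
        double rq = (rel[k + nr] == std::numeric_limits<double>::max()) ? 1e30 : rel[k + nr];
        edges.push_back({rk + rq, k, k + nr});
      }
    }
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge& a, const Edge& b) { return a.r < b.r; });

  // union-find with explicit member lists so group offsets can be applied
  std::vector<int> head(n), next(n, -1), tail(n), grp(n), size(n, 1);
  for (int k = 0; k < n; ++k) { head[k] = k; tail[k] = k; grp[k] = k; }

  for (const Edge& e : edges) {
    int gp = grp[e.p], gq = grp[e.q];
    if (gp == gq) continue;
    // adjacent pixels: true difference assumed in (-pi, pi]; the rounded
    // multiple of 2*pi is the wrap correction for q's group relative to p's
    double shift = TWOPI * std::round((val[e.p] - val[e.q]) / TWOPI);
    // merge the smaller group into the larger
    int glarge = gp, gsmall = gq;
    double add = shift;            // applied to members of gsmall (= q's side)
    if (size[gp] < size[gq]) { glarge = gq; gsmall = gp; add = -shift; }
    for (int k = head[gsmall]; k != -1; k = next[k]) {
      val[k] += add;
      grp[k] = glarge;
    }
    next[tail[glarge]] = head[gsmall];
    tail[glarge] = tail[gsmall];
    size[glarge] += size[gsmall];
  }

  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = val[i + j * nr];
  return out;
}

// 3x3 median filter with edge replication.
// [[Rcpp::export(name = ".cpp_median3")]]
NumericMatrix cpp_median3(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  double buf[9];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int m = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -1; di <= 1; ++di) {
          int ii = std::min(std::max(i + di, 0), nr - 1);
          buf[m++] = x(ii, jj);
        }
      }
      std::nth_element(buf, buf + 4, buf + 9);
      out(i, j) = buf[4];
    }
  }
  return out;
}
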