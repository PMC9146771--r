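#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Scanline even-odd polygon fill at integer pixel centers.
// Pixel (r, c) (0-based) has center (x = c, y = r); vertices are (x, y),
// closed implicitly (last vertex connects to the first).
// [[Rcpp::export(name = ".cpp_rasterize")]]
IntegerMatrix cpp_rasterize(NumericMatrix pts, int nrow, int ncol) {
  IntegerMatrix mask(nrow, ncol);
  int n = pts.nrow();
  if (n < 3) return mask;
  std::vector<double> xs;
  for (int r = 0; r < nrow; ++r) {
    double y = (double)r;
    xs.clear();
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      double y1 = pts(i, 1), y2 = pts(j, 1);
      double x1 = pts(i, 0), x2 = pts(j, 0);
      // half-open rule so shared vertices are counted once
      if ((y1 <= y && y < y2) || (y2 <= y && y < y1)) {
        xs.push_back(x1 + (y - y1) * (x2 - x1) / (y2 - y1));
      }
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int c0 = (int)std::ceil(xs[k]);
      if ((double)c0 == xs[k]) c0 += 1;  // strict interior
      int c1 = (int)std::floor(xs[k + 1]);
      if ((double)c1 == xs[k + 1]) c1 -= 1;
      c0 = std::max(c0, 0);
      c1 = std::min(c1, ncol - 1);
      for (int c = c0; c <= c1; ++c) mask(r, c) = 1;
    }
  }
  return mask;
}

// Connected-component labeling, connectivity 4 or 8 (flood fill).
// [[Rcpp::export(name = ".cpp_label")]]
IntegerMatrix cpp_label(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({r, c});
      lab(r, c) = next;
      while (!stack.empty()) {
        auto p = stack.back();
        stack.pop_back();
        for (int k = 0; k < nn; ++k) {
          int rr = p.first + dr[k], cc = p.second + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back({rr, cc});
          }
        }
      }
    }
  }
  return lab;
}

// First-order fast marching for |grad d| = 1 from frozen seed pixels.
// seeds: matrix with columns (row0, col0, dist) — 0-based pixel indices.
// [[Rcpp::export(name = ".cpp_fast_march")]]
NumericMatrix cpp_fast_march(NumericMatrix seeds, int nrow, int ncol) {
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix d(nrow, ncol);
  std::fill(d.begin(), d.end(), INF);
  std::vector<char> frozen(nrow * ncol, 0);
  typedef std::pair<double, int> Node;  // (dist, linear index r + c*nrow)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node>> heap;
  for (int i = 0; i < seeds.nrow(); ++i) {
    int r = (int)seeds(i, 0), c = (int)seeds(i, 1);
    if (r < 0 || r >= nrow || c < 0 || c >= ncol) continue;
    double v = seeds(i, 2);
    if (v < d(r, c)) {
      d(r, c) = v;
      heap.push({v, r + c * nrow});
    }
  }
  const int dr[] = {-1, 1, 0, 0}, dc[] = {0, 0, -1, 1};
  while (!heap.empty()) {
    Node nd = heap.top();
    heap.pop();
    int idx = nd.second, r = idx % nrow, c = idx / nrow;
    if (frozen[idx]) continue;
    frozen[idx] = 1;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
      int jdx = rr + cc * nrow;
      if (frozen[jdx]) continue;
      double a = INF, b = INF;  // min frozen-or-known neighbor along rows / cols
      if (rr > 0) a = std::min(a, d(rr - 1, cc));
      if (rr < nrow - 1) a = std::min(a, d(rr + 1, cc));
      if (cc > 0) b = std::min(b, d(rr, cc - 1));
      if (cc < ncol - 1) b = std::min(b, d(rr, cc + 1));
      double lo = std::min(a, b), hi = std::max(a, b), cand;
      if (!std::isfinite(lo)) continue;
      if (!std::isfinite(hi) || hi - lo >= 1.0) {
        cand = lo + 1.0;
      } else {
        cand = 0.5 * (a + b + std::sqrt(2.0 - (a - b) * (a - b)));
      }
      if (cand < d(rr, cc)) {
        d(rr, cc) = cand;
        heap.push({cand, jdx});
      }
    }
  }
  return d;
}
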