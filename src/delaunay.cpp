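#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Incremental Bowyer-Watson Delaunay triangulation of a 2-D point set.
// Deterministic for a given input order; callers are expected to break
// exact cocircularities by a tiny deterministic jitter on the coordinates
// they pass in (the returned triangles index the original points).

struct Tri {
  int a, b, c;
  double cx, cy, r2;   // circumcircle
  bool alive;
};

static inline bool circumcircle(const std::vector<double>& px,
                                const std::vector<double>& py,
                                int a, int b, int c, Tri& t) {
  const double ax = px[a], ay = py[a];
  const double bx = px[b], by = py[b];
  const double cx = px[c], cy = py[c];
  const double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-300) return false;
  const double a2 = ax * ax + ay * ay;
  const double b2 = bx * bx + by * by;
  const double c2 = cx * cx + cy * cy;
  t.cx = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  t.cy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  const double dx = ax - t.cx, dy = ay - t.cy;
  t.r2 = dx * dx + dy * dy;
  return true;
}

// [[Rcpp::export]]
IntegerMatrix delaunay_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3) stop("need at least 3 points");

  // scale into the unit box for numerical sanity
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, (double)x[i]); xmax = std::max(xmax, (double)x[i]);
    ymin = std::min(ymin, (double)y[i]); ymax = std::max(ymax, (double)y[i]);
  }
  const double span = std::max(xmax - xmin, ymax - ymin);
  if (!(span > 0)) stop("degenerate point set");
  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) {
    px[i] = (x[i] - xmin) / span;
    py[i] = (y[i] - ymin) / span;
  }
  // super-triangle
  px[n] = -100.0;  py[n] = -100.0;
  px[n + 1] = 101.0; py[n + 1] = -100.0;
  px[n + 2] = 0.5;  py[n + 2] = 150.0;

  std::vector<Tri> tris;
  tris.reserve(4 * n);
  Tri t0{ n, n + 1, n + 2, 0, 0, 0, true };
  if (!circumcircle(px, py, t0.a, t0.b, t0.c, t0)) stop("super-triangle failure");
  tris.push_back(t0);

  std::vector<int> bad;
  // cavity boundary edges
  std::vector<std::pair<int, int> > edges;
  for (int i = 0; i < n; ++i) {
    bad.clear();
    edges.clear();
    const double pxi = px[i], pyi = py[i];
    for (int t = 0; t < (int)tris.size(); ++t) {
      if (!tris[t].alive) continue;
      const double dx = pxi - tris[t].cx, dy = pyi - tris[t].cy;
      if (dx * dx + dy * dy <= tris[t].r2 * (1.0 + 1e-12)) bad.push_back(t);
    }
    if (bad.empty()) stop("point %d not inside any circumcircle", i + 1);
    for (size_t k = 0; k < bad.size(); ++k) {
      Tri& tt = tris[bad[k]];
      tt.alive = false;
      const int e[3][2] = { {tt.a, tt.b}, {tt.b, tt.c}, {tt.c, tt.a} };
      for (int j = 0; j < 3; ++j) {
        bool shared = false;
        for (size_t m = 0; m < edges.size(); ++m) {
          if ((edges[m].first == e[j][1] && edges[m].second == e[j][0]) ||
              (edges[m].first == e[j][0] && edges[m].second == e[j][1])) {
            edges[m].first = -1;  // interior edge, cancel
            shared = true;
            break;
          }
        }
        if (!shared) edges.push_back(std::make_pair(e[j][0], e[j][1]));
      }
    }
    for (size_t m = 0; m < edges.size(); ++m) {
      if (edges[m].first < 0) continue;
      Tri nt{ edges[m].first, edges[m].second, i, 0, 0, 0, true };
      if (!circumcircle(px, py, nt.a, nt.b, nt.c, nt)) continue;  // collinear sliver
      tris.push_back(nt);
    }
  }

  // collect triangles not touching the super-triangle, CCW-oriented
  std::vector<int> keep;
  for (int t = 0; t < (int)tris.size(); ++t) {
    if (!tris[t].alive) continue;
    if (tris[t].a >= n || tris[t].b >= n || tris[t].c >= n) continue;
    keep.push_back(t);
  }
  IntegerMatrix out(keep.size(), 3);
  for (size_t k = 0; k < keep.size(); ++k) {
    int a = tris[keep[k]].a, b = tris[keep[k]].b, c = tris[keep[k]].c;
    const double cr = (px[b] - px[a]) * (py[c] - py[a]) -
                      (py[b] - py[a]) * (px[c] - px[a]);
    if (cr < 0) std::swap(b, c);
    out(k, 0) = a + 1;  // 1-based for R
    out(k, 1) = b + 1;
    out(k, 2) = c + 1;
  }
  return out;
}
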