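#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <utility>
#include <algorithm>

using namespace Rcpp;

// Bowyer-Watson incremental Delaunay triangulation with a symbolic ghost
// vertex: the convex hull is bounded by "ghost triangles" (a directed hull
// edge plus the point at infinity) whose conflict test is a pure orientation
// predicate. This avoids the precision/geometry failure modes of a finite
// super-triangle (real triangles near collinear point triples have
// circumcircles large enough to reach any finite enclosure). Points are
// jittered upstream so no four inputs are exactly cocircular.

namespace {

const int GHOST = -1;

struct Tri {
  int a, b, c;  // c == GHOST for ghost triangles; real triangles CCW;
                // ghost triangles conflict iff orient(a, b, p) > 0
  bool alive;
};

inline double orient2d(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix delaunay_edges_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3) return IntegerMatrix(0, 2);

  std::vector<double> px(x.begin(), x.end());
  std::vector<double> py(y.begin(), y.end());

  // Incircle determinant for a CCW real triangle: positive when q is
  // strictly inside the circumcircle.
  auto in_circle = [&](const Tri& t, double qx, double qy) -> bool {
    if (t.c == GHOST) {
      return orient2d(px[t.a], py[t.a], px[t.b], py[t.b], qx, qy) > 0.0;
    }
    const double adx = px[t.a] - qx, ady = py[t.a] - qy;
    const double bdx = px[t.b] - qx, bdy = py[t.b] - qy;
    const double cdx = px[t.c] - qx, cdy = py[t.c] - qy;
    const double ad = adx * adx + ady * ady;
    const double bd = bdx * bdx + bdy * bdy;
    const double cd = cdx * cdx + cdy * cdy;
    const double det = adx * (bdy * cd - bd * cdy)
                     - ady * (bdx * cd - bd * cdx)
                     + ad  * (bdx * cdy - bdy * cdx);
    return det > 0.0;
  };

  std::vector<Tri> tris;
  tris.reserve(6 * n);
  {
    Tri t{0, 1, 2, true};
    if (orient2d(px[0], py[0], px[1], py[1], px[2], py[2]) < 0.0)
      std::swap(t.b, t.c);
    tris.push_back(t);
    // Ghost triangles on the three hull edges, directed so that "outside"
    // is the conflict side.
    tris.push_back(Tri{t.b, t.a, GHOST, true});
    tris.push_back(Tri{t.c, t.b, GHOST, true});
    tris.push_back(Tri{t.a, t.c, GHOST, true});
  }

  double cx_sum = px[0] + px[1] + px[2];
  double cy_sum = py[0] + py[1] + py[2];

  std::vector<int> bad;
  typedef std::pair<int, int> Edge;
  std::map<Edge, int> edge_count;

  for (int p = 3; p < n; ++p) {
    cx_sum += px[p];
    cy_sum += py[p];
    const double cenx = cx_sum / (p + 1), ceny = cy_sum / (p + 1);

    bad.clear();
    for (int ti = 0; ti < (int)tris.size(); ++ti) {
      if (tris[ti].alive && in_circle(tris[ti], px[p], py[p]))
        bad.push_back(ti);
    }
    edge_count.clear();
    for (int bi : bad) {
      const Tri& t = tris[bi];
      const int vs[3][2] = {{t.a, t.b}, {t.b, t.c}, {t.c, t.a}};
      for (int k = 0; k < 3; ++k) {
        Edge e(std::min(vs[k][0], vs[k][1]), std::max(vs[k][0], vs[k][1]));
        edge_count[e] += 1;
      }
      tris[bi].alive = false;
    }
    for (std::map<Edge, int>::const_iterator it = edge_count.begin();
         it != edge_count.end(); ++it) {
      if (it->second != 1) continue;
      const int u = it->first.first, v = it->first.second;  // u may be GHOST
      if (u == GHOST) {
        // New hull edge {v, p}: direct it so the interior centroid lies on
        // the non-conflict side.
        Tri t{v, p, GHOST, true};
        if (orient2d(px[t.a], py[t.a], px[t.b], py[t.b], cenx, ceny) > 0.0)
          std::swap(t.a, t.b);
        tris.push_back(t);
      } else {
        Tri t{u, v, p, true};
        if (orient2d(px[t.a], py[t.a], px[t.b], py[t.b], px[t.c], py[t.c]) < 0.0)
          std::swap(t.a, t.b);
        tris.push_back(t);
      }
    }
    if ((int)tris.size() > 10 * (p + 4)) {
      std::vector<Tri> live;
      live.reserve(tris.size());
      for (const Tri& t : tris) if (t.alive) live.push_back(t);
      tris.swap(live);
    }
  }

  std::map<Edge, bool> edges;
  for (const Tri& t : tris) {
    if (!t.alive || t.c == GHOST) continue;
    const int vs[3][2] = {{t.a, t.b}, {t.b, t.c}, {t.c, t.a}};
    for (int k = 0; k < 3; ++k) {
      Edge e(std::min(vs[k][0], vs[k][1]), std::max(vs[k][0], vs[k][1]));
      edges[e] = true;
    }
  }

  IntegerMatrix out(edges.size(), 2);
  int r = 0;
  for (std::map<Edge, bool>::const_iterator it = edges.begin();
       it != edges.end(); ++it, ++r) {
    out(r, 0) = it->first.first + 1;  // back to 1-based
    out(r, 1) = it->first.second + 1;
  }
  return out;
}
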