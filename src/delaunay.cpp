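// Incremental Bowyer-Watson Delaunay triangulation with triangle adjacency
// and walking point location. Four numeric guard vertices placed ~1e12 times
// the data extent away stand in for the point at infinity; triangles touching
// a guard encode convex-hull adjacency, so hull edges between real points are
// retained (open-boundary Voronoi cells keep their adjacencies).
//
// Degeneracy policy: every input point receives a deterministic jitter of
// magnitude 1e-9 * extent drawn from a fixed-seed splitmix64 stream before
// tessellation. This breaks co-circular quadruples (square lattices) the same
// way on every run; neighbor distances are computed by the callers on the
// unperturbed coordinates, so the jitter never enters the histograms.

#include "delaunay.h"
#include <Rcpp.h>
#include <array>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>

namespace {

const double JITTER_REL = 1e-9;
const double GUARD_REL = 1e12;
const uint64_t JITTER_SEED = 0x5EEDC0FFEEULL;

inline double splitmix_u01(uint64_t &s) {
  s += 0x9e3779b97f4a7c15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  z ^= z >> 31;
  return (double)(z >> 11) * (1.0 / 9007199254740992.0);
}

inline double orient(double ax, double ay, double bx, double by, double cx,
                     double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

struct Triangulation {
  std::vector<double> x, y; // n real vertices then 4 guards
  int nreal;
  std::vector<std::array<int, 3>> tv; // vertices, CCW
  std::vector<std::array<int, 3>> ta; // neighbor across edge opposite vertex k
  std::vector<char> dead;
  std::vector<int> stamp; // cavity BFS marks
  int cur_stamp = 0;
  int hint = 0;

  // p strictly inside circumcircle of alive CCW triangle t
  bool incircle(int t, int p) const {
    const std::array<int, 3> &v = tv[t];
    const double px = x[p], py = y[p];
    const double ax = x[v[0]] - px, ay = y[v[0]] - py;
    const double bx = x[v[1]] - px, by = y[v[1]] - py;
    const double cx = x[v[2]] - px, cy = y[v[2]] - py;
    const double a2 = ax * ax + ay * ay;
    const double b2 = bx * bx + by * by;
    const double c2 = cx * cx + cy * cy;
    const double det = ax * (by * c2 - b2 * cy) - ay * (bx * c2 - b2 * cx) +
                       a2 * (bx * cy - by * cx);
    return det > 0.0;
  }

  bool contains(int t, int p) const {
    const std::array<int, 3> &v = tv[t];
    for (int k = 0; k < 3; ++k) {
      int a = v[(k + 1) % 3], b = v[(k + 2) % 3];
      if (orient(x[a], y[a], x[b], y[b], x[p], y[p]) < 0.0) return false;
    }
    return true;
  }

  int locate(int p) {
    int t = hint;
    if (t < 0 || t >= (int)tv.size() || dead[t]) t = first_alive();
    long maxit = 100 + 4L * (long)tv.size();
    for (long it = 0; it < maxit; ++it) {
      bool moved = false;
      const std::array<int, 3> &v = tv[t];
      for (int k = 0; k < 3; ++k) {
        int a = v[(k + 1) % 3], b = v[(k + 2) % 3];
        if (orient(x[a], y[a], x[b], y[b], x[p], y[p]) < 0.0 &&
            ta[t][k] >= 0) {
          t = ta[t][k];
          moved = true;
          break;
        }
      }
      if (!moved) return t;
    }
    // Degenerate walk cycle: fall back to exhaustive scan.
    for (int u = 0; u < (int)tv.size(); ++u)
      if (!dead[u] && contains(u, p)) return u;
    for (int u = 0; u < (int)tv.size(); ++u)
      if (!dead[u] && incircle(u, p)) return u;
    Rcpp::stop("delaunay: point location failed (degenerate input)");
  }

  int first_alive() const {
    for (int u = (int)tv.size() - 1; u >= 0; --u)
      if (!dead[u]) return u;
    Rcpp::stop("delaunay: empty triangulation");
  }

  void insert(int p) {
    int seed = locate(p);
    ++cur_stamp;
    std::vector<int> bad;
    std::vector<int> queue;
    bad.push_back(seed);
    queue.push_back(seed);
    stamp[seed] = cur_stamp;
    // boundary edge: (a, b) CCW in its bad triangle, outer triangle index
    struct BEdge {
      int a, b, outer;
    };
    std::vector<BEdge> boundary;
    while (!queue.empty()) {
      int t = queue.back();
      queue.pop_back();
      for (int k = 0; k < 3; ++k) {
        int u = ta[t][k];
        int a = tv[t][(k + 1) % 3], b = tv[t][(k + 2) % 3];
        if (u >= 0 && stamp[u] == cur_stamp) continue; // already in cavity
        if (u >= 0 && incircle(u, p)) {
          stamp[u] = cur_stamp;
          bad.push_back(u);
          queue.push_back(u);
        } else {
          boundary.push_back({a, b, u});
        }
      }
    }
    // Re-walk: some boundary edges may have been recorded before their outer
    // triangle joined the cavity; drop those.
    std::vector<BEdge> rim;
    rim.reserve(boundary.size());
    for (const BEdge &e : boundary)
      if (e.outer < 0 || stamp[e.outer] != cur_stamp) rim.push_back(e);

    // New triangles (p, a, b) around the cavity rim.
    std::vector<int> start_of(rim.size());
    std::unordered_map<int, int> by_start;
    by_start.reserve(rim.size() * 2);
    std::vector<int> created;
    created.reserve(rim.size());
    for (size_t e = 0; e < rim.size(); ++e) {
      int idx = (int)tv.size();
      tv.push_back({p, rim[e].a, rim[e].b});
      ta.push_back({rim[e].outer, -1, -1});
      dead.push_back(0);
      stamp.push_back(0);
      created.push_back(idx);
      by_start[rim[e].a] = idx;
      // fix outer's back-pointer
      int out = rim[e].outer;
      if (out >= 0) {
        for (int k = 0; k < 3; ++k) {
          int oa = tv[out][(k + 1) % 3], ob = tv[out][(k + 2) % 3];
          if ((oa == rim[e].b && ob == rim[e].a)) {
            ta[out][k] = idx;
            break;
          }
        }
      }
    }
    // Link new triangles to each other around p: edge (b, p) of triangle
    // (p, a, b) is shared with the rim triangle starting at b; edge (p, a)
    // with the rim triangle ending at a (i.e., whose start s has edge (s, a)).
    for (size_t e = 0; e < rim.size(); ++e) {
      int idx = created[e];
      ta[idx][1] = by_start[rim[e].b]; // across edge (b, p), opposite a
      // across edge (p, a), opposite b: triangle whose edge ends at a
      // cavity rim is a closed cycle, so predecessor exists in by_start via
      // search below
    }
    // predecessor links: for each rim edge (a,b), triangle with edge (?, a)
    // is the one whose second rim vertex is a; build map end -> idx
    std::unordered_map<int, int> by_end;
    by_end.reserve(rim.size() * 2);
    for (size_t e = 0; e < rim.size(); ++e) by_end[rim[e].b] = created[e];
    for (size_t e = 0; e < rim.size(); ++e)
      ta[created[e]][2] = by_end[rim[e].a];

    for (int t : bad) dead[t] = 1;
    if (!created.empty()) hint = created.back();
  }
};

// Build the triangulation of the given (already combined) coordinate arrays.
// Returns unique undirected vertex pairs among the first `nkeep`... (all real
// vertices); guards excluded.
std::vector<std::pair<int, int>> triangulate_pairs(std::vector<double> px,
                                                   std::vector<double> py) {
  const int n = (int)px.size();
  std::vector<std::pair<int, int>> out;
  if (n < 2) return out;
  if (n == 2) { // no tessellation; callers enforce preconditions
    out.push_back({0, 1});
    return out;
  }
  double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, px[i]);
    xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]);
    ymax = std::max(ymax, py[i]);
  }
  double ext = std::max({xmax - xmin, ymax - ymin, 1e-12});
  // deterministic symmetric perturbation for reproducible tie-breaking
  uint64_t s = JITTER_SEED;
  for (int i = 0; i < n; ++i) {
    px[i] += (2.0 * splitmix_u01(s) - 1.0) * JITTER_REL * ext;
    py[i] += (2.0 * splitmix_u01(s) - 1.0) * JITTER_REL * ext;
  }
  const double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  const double D = GUARD_REL * ext;

  Triangulation T;
  T.nreal = n;
  T.x = std::move(px);
  T.y = std::move(py);
  // guards: large convex, deliberately non-co-circular quad, CCW
  T.x.push_back(cx - 1.00 * D); T.y.push_back(cy - 0.83 * D);
  T.x.push_back(cx + 1.02 * D); T.y.push_back(cy - 0.80 * D);
  T.x.push_back(cx + 0.98 * D); T.y.push_back(cy + 0.77 * D);
  T.x.push_back(cx - 1.03 * D); T.y.push_back(cy + 0.90 * D);
  const int g0 = n, g1 = n + 1, g2 = n + 2, g3 = n + 3;
  T.tv.push_back({g0, g1, g2});
  T.tv.push_back({g0, g2, g3});
  T.ta.push_back({-1, 1, -1}); // across (g1,g2), (g2,g0), (g0,g1)
  T.ta.push_back({-1, -1, 0}); // across (g2,g3), (g3,g0), (g0,g2)
  T.dead.assign(2, 0);
  T.stamp.assign(2, 0);
  T.hint = 0;

  for (int p = 0; p < n; ++p) T.insert(p);

  std::unordered_set<long long> seen;
  seen.reserve(6 * n);
  for (int t = 0; t < (int)T.tv.size(); ++t) {
    if (T.dead[t]) continue;
    for (int k = 0; k < 3; ++k) {
      int a = T.tv[t][k], b = T.tv[t][(k + 1) % 3];
      if (a >= n || b >= n) continue;
      int lo = std::min(a, b), hi = std::max(a, b);
      long long key = (long long)lo * (long long)n + hi;
      if (seen.insert(key).second) out.push_back({lo, hi});
    }
  }
  return out;
}

} // namespace

std::vector<std::pair<int, int>> delaunay_pairs(const std::vector<double> &x,
                                                const std::vector<double> &y) {
  return triangulate_pairs(x, y);
}

std::vector<std::pair<int, int>> periodic_delaunay_pairs(
    const std::vector<double> &x, const std::vector<double> &y, double Lx,
    double Ly) {
  const int n = (int)x.size();
  std::vector<double> tx, ty;
  tx.reserve(9 * n);
  ty.reserve(9 * n);
  // canonical tile first so tiled index % n maps back to the original index
  for (int oy = 0; oy <= 2; ++oy) {
    for (int ox = 0; ox <= 2; ++ox) {
      double sx = (ox == 2 ? -Lx : ox * Lx); // offsets 0, +L, -L
      double sy = (oy == 2 ? -Ly : oy * Ly);
      for (int i = 0; i < n; ++i) {
        tx.push_back(x[i] + sx);
        ty.push_back(y[i] + sy);
      }
    }
  }
  std::vector<std::pair<int, int>> pairs = triangulate_pairs(tx, ty);
  std::unordered_set<long long> seen;
  std::vector<std::pair<int, int>> out;
  for (auto &pr : pairs) {
    int u = pr.first, v = pr.second;
    if (u >= n && v >= n) continue; // keep edges touching the canonical tile
    int a = u % n, b = v % n;
    if (a == b) continue; // no self-edges (point adjacent to its own image)
    int lo = std::min(a, b), hi = std::max(a, b);
    long long key = (long long)lo * (long long)n + hi;
    if (seen.insert(key).second) out.push_back({lo, hi});
  }
  return out;
}

// [[Rcpp::export(name = ".delaunay_edges_cpp")]]
Rcpp::IntegerMatrix delaunay_edges_cpp(Rcpp::NumericMatrix pts) {
  int n = pts.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pts(i, 0);
    y[i] = pts(i, 1);
  }
  auto pairs = delaunay_pairs(x, y);
  Rcpp::IntegerMatrix out(pairs.size(), 2);
  for (size_t e = 0; e < pairs.size(); ++e) {
    out(e, 0) = pairs[e].first + 1;
    out(e, 1) = pairs[e].second + 1;
  }
  return out;
}

// [[Rcpp::export(name = ".periodic_delaunay_edges_cpp")]]
Rcpp::IntegerMatrix periodic_delaunay_edges_cpp(Rcpp::NumericMatrix pts,
                                                double Lx, double Ly) {
  int n = pts.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pts(i, 0);
    y[i] = pts(i, 1);
  }
  auto pairs = periodic_delaunay_pairs(x, y, Lx, Ly);
  Rcpp::IntegerMatrix out(pairs.size(), 2);
  for (size_t e = 0; e < pairs.size(); ++e) {
    out(e, 0) = pairs[e].first + 1;
    out(e, 1) = pairs[e].second + 1;
  }
  return out;
}
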