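#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <unordered_set>
using namespace Rcpp;

// Quickhull in 3D, volume only. Faces carry outside point sets; the horizon
// of each inserted apex is found by scanning live faces (adequate for the
// tens of thousands of points a downsampled bunch scan produces). Degenerate
// inputs (fewer than 4 points, collinear or coplanar sets) yield volume 0.

namespace {

struct Vec {
  double x, y, z;
};
inline Vec sub(const Vec &a, const Vec &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec cross(const Vec &a, const Vec &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const Vec &a, const Vec &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(const Vec &a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;          // vertex indices, wound so the normal points outward
  Vec n;                // unit outward normal
  double off;           // plane offset: dot(n, p) = off on the plane
  bool alive;
  std::vector<int> outside;
};

struct Hull {
  std::vector<Vec> P;
  std::vector<Face> F;
  Vec interior;
  double eps;

  double height(const Face &f, int p) const { return dot(f.n, P[p]) - f.off; }

  // create a face on points (a,b,c), oriented away from the interior point
  int add_face(int a, int b, int c) {
    Face f;
    f.a = a; f.b = b; f.c = c;
    Vec n = cross(sub(P[b], P[a]), sub(P[c], P[a]));
    double len = norm(n);
    if (len < 1e-300) len = 1;
    f.n = {n.x / len, n.y / len, n.z / len};
    f.off = dot(f.n, P[a]);
    if (dot(f.n, interior) - f.off > 0) {
      std::swap(f.b, f.c);
      f.n = {-f.n.x, -f.n.y, -f.n.z};
      f.off = -f.off + 2 * dot(f.n, P[f.a]); // recompute cleanly below
      f.off = dot(f.n, P[f.a]);
    }
    f.alive = true;
    F.push_back(f);
    return (int)F.size() - 1;
  }
};

} // namespace

// [[Rcpp::export(rng = false)]]
double cpp_convex_hull_volume(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) return 0.0;
  Hull H;
  H.P.resize(n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    H.P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double v[3] = {H.P[i].x, H.P[i].y, H.P[i].z};
    for (int a = 0; a < 3; ++a) {
      if (v[a] < lo[a]) lo[a] = v[a];
      if (v[a] > hi[a]) hi[a] = v[a];
    }
  }
  double extent = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2]});
  if (!(extent > 0)) return 0.0;
  H.eps = 1e-10 * extent;

  // initial simplex: farthest pair among axis extremes, then farthest from
  // the line, then farthest from the plane
  std::vector<int> extremes;
  for (int a = 0; a < 3; ++a) {
    int imin = 0, imax = 0;
    for (int i = 1; i < n; ++i) {
      double v = a == 0 ? H.P[i].x : (a == 1 ? H.P[i].y : H.P[i].z);
      double vmin = a == 0 ? H.P[imin].x : (a == 1 ? H.P[imin].y : H.P[imin].z);
      double vmax = a == 0 ? H.P[imax].x : (a == 1 ? H.P[imax].y : H.P[imax].z);
      if (v < vmin) imin = i;
      if (v > vmax) imax = i;
    }
    extremes.push_back(imin);
    extremes.push_back(imax);
  }
  int v0 = extremes[0], v1 = extremes[1];
  double best = -1;
  for (size_t i = 0; i < extremes.size(); ++i)
    for (size_t j = i + 1; j < extremes.size(); ++j) {
      double d = norm(sub(H.P[extremes[i]], H.P[extremes[j]]));
      if (d > best) { best = d; v0 = extremes[i]; v1 = extremes[j]; }
    }
  if (best < H.eps) return 0.0;

  Vec dir = sub(H.P[v1], H.P[v0]);
  double dl = norm(dir);
  dir = {dir.x / dl, dir.y / dl, dir.z / dl};
  int v2 = -1;
  best = H.eps;
  for (int i = 0; i < n; ++i) {
    Vec w = sub(H.P[i], H.P[v0]);
    double t = dot(w, dir);
    Vec perp = {w.x - t * dir.x, w.y - t * dir.y, w.z - t * dir.z};
    double d = norm(perp);
    if (d > best) { best = d; v2 = i; }
  }
  if (v2 < 0) return 0.0;  // collinear

  Vec pn = cross(sub(H.P[v1], H.P[v0]), sub(H.P[v2], H.P[v0]));
  double pl = norm(pn);
  pn = {pn.x / pl, pn.y / pl, pn.z / pl};
  double poff = dot(pn, H.P[v0]);
  int v3 = -1;
  best = H.eps;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(dot(pn, H.P[i]) - poff);
    if (d > best) { best = d; v3 = i; }
  }
  if (v3 < 0) return 0.0;  // coplanar

  H.interior = {(H.P[v0].x + H.P[v1].x + H.P[v2].x + H.P[v3].x) / 4,
                (H.P[v0].y + H.P[v1].y + H.P[v2].y + H.P[v3].y) / 4,
                (H.P[v0].z + H.P[v1].z + H.P[v2].z + H.P[v3].z) / 4};
  H.add_face(v0, v1, v2);
  H.add_face(v0, v1, v3);
  H.add_face(v0, v2, v3);
  H.add_face(v1, v2, v3);

  // initial conflict assignment
  for (int i = 0; i < n; ++i) {
    if (i == v0 || i == v1 || i == v2 || i == v3) continue;
    for (auto &f : H.F) {
      if (H.height(f, i) > H.eps) { f.outside.push_back(i); break; }
    }
  }

  std::vector<int> pending;
  for (int fi = 0; fi < (int)H.F.size(); ++fi)
    if (!H.F[fi].outside.empty()) pending.push_back(fi);

  while (!pending.empty()) {
    int fi = pending.back();
    pending.pop_back();
    if (fi >= (int)H.F.size() || !H.F[fi].alive || H.F[fi].outside.empty())
      continue;
    Face &f = H.F[fi];
    int apex = f.outside[0];
    double hbest = H.height(f, apex);
    for (int p : f.outside) {
      double h = H.height(f, p);
      if (h > hbest) { hbest = h; apex = p; }
    }

    // visible faces (global scan) and their directed edges
    std::vector<int> visible;
    std::unordered_set<long long> vedges;
    for (int gi = 0; gi < (int)H.F.size(); ++gi) {
      Face &g = H.F[gi];
      if (!g.alive) continue;
      if (H.height(g, apex) > H.eps) {
        visible.push_back(gi);
        int e[3][2] = {{g.a, g.b}, {g.b, g.c}, {g.c, g.a}};
        for (auto &ed : e)
          vedges.insert((long long)ed[0] * n + ed[1]);
      }
    }
    std::vector<int> orphans;
    for (int gi : visible) {
      Face &g = H.F[gi];
      g.alive = false;
      for (int p : g.outside)
        if (p != apex) orphans.push_back(p);
      g.outside.clear();
    }
    std::vector<int> fresh;
    for (int gi : visible) {
      // horizon edges: directed edge present, reverse absent
      Face g = H.F[gi];
      int e[3][2] = {{g.a, g.b}, {g.b, g.c}, {g.c, g.a}};
      for (auto &ed : e) {
        if (vedges.count((long long)ed[1] * n + ed[0])) continue;
        fresh.push_back(H.add_face(ed[0], ed[1], apex));
      }
    }
    for (int p : orphans) {
      for (int gi : fresh) {
        if (H.height(H.F[gi], p) > H.eps) {
          H.F[gi].outside.push_back(p);
          break;
        }
      }
    }
    for (int gi : fresh)
      if (!H.F[gi].outside.empty()) pending.push_back(gi);
  }

  double vol = 0;
  for (auto &f : H.F) {
    if (!f.alive) continue;
    Vec a = sub(H.P[f.a], H.interior);
    Vec b = sub(H.P[f.b], H.interior);
    Vec c = sub(H.P[f.c], H.interior);
    vol += dot(a, cross(b, c)) / 6.0;
  }
  return std::fabs(vol);
}
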