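#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 3D convex hull (quickhull with per-face conflict lists).
// Returns 1-based triangle indices into the input point matrix, with
// outward-oriented normals. Errors on degenerate (coplanar) input.

namespace {

struct V3 {
  double x, y, z;
  V3 operator-(const V3& o) const { return {x - o.x, y - o.y, z - o.z}; }
  V3 operator+(const V3& o) const { return {x + o.x, y + o.y, z + o.z}; }
  V3 operator*(double s) const { return {x * s, y * s, z * s}; }
};
inline V3 cross(const V3& a, const V3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;          // point indices, counter-clockwise seen from outside
  V3 n;                 // unit normal
  double d;             // plane offset: dot(n, p) = d on the plane
  int nb[3];            // neighbour face across edge (a,b), (b,c), (c,a)
  std::vector<int> outside;  // conflict list
  int far_pt = -1;
  double far_dist = 0.0;
  bool alive = true;
};

struct Hull {
  const NumericMatrix& P;
  std::vector<Face> faces;
  double eps;

  explicit Hull(const NumericMatrix& pts) : P(pts) {}

  V3 pt(int i) const { return {P(i, 0), P(i, 1), P(i, 2)}; }

  double dist(int f, int p) const { return dot(faces[f].n, pt(p)) - faces[f].d; }

  void set_plane(Face& f) {
    V3 u = pt(f.b) - pt(f.a), v = pt(f.c) - pt(f.a);
    V3 n = cross(u, v);
    double ln = norm(n);
    f.n = n * (1.0 / std::max(ln, 1e-300));
    f.d = dot(f.n, pt(f.a));
  }

  // assign points to the first face that sees them
  void distribute(const std::vector<int>& pts_in, const std::vector<int>& face_ids) {
    for (int p : pts_in) {
      for (int fi : face_ids) {
        Face& f = faces[fi];
        if (!f.alive) continue;
        double d = dot(f.n, pt(p)) - f.d;
        if (d > eps) {
          f.outside.push_back(p);
          if (d > f.far_dist) { f.far_dist = d; f.far_pt = p; }
          break;
        }
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_convex_hull")]]
IntegerMatrix cpp_convex_hull(NumericMatrix points) {
  const int n = points.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  Hull H(points);

  // scale-aware tolerance
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], points(i, d));
      hi[d] = std::max(hi[d], points(i, d));
    }
  double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                          (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                          (hi[2] - lo[2]) * (hi[2] - lo[2]));
  if (diag <= 0) stop("degenerate input: all points coincide");
  H.eps = 1e-10 * diag + 1e-12;

  // initial simplex: two extreme points, then farthest from line, then plane
  int i0 = 0, i1 = 0;
  {
    double best = -1;
    int ext[6];
    for (int d = 0; d < 3; ++d) {
      int mn = 0, mx = 0;
      for (int i = 1; i < n; ++i) {
        if (points(i, d) < points(mn, d)) mn = i;
        if (points(i, d) > points(mx, d)) mx = i;
      }
      ext[2 * d] = mn; ext[2 * d + 1] = mx;
    }
    for (int a = 0; a < 6; ++a)
      for (int b = a + 1; b < 6; ++b) {
        V3 dif = H.pt(ext[a]) - H.pt(ext[b]);
        double l = dot(dif, dif);
        if (l > best) { best = l; i0 = ext[a]; i1 = ext[b]; }
      }
  }
  int i2 = -1;
  {
    double best = H.eps;
    V3 u = H.pt(i1) - H.pt(i0);
    for (int i = 0; i < n; ++i) {
      double l = norm(cross(u, H.pt(i) - H.pt(i0))) / std::max(norm(u), 1e-300);
      if (l > best) { best = l; i2 = i; }
    }
    if (i2 < 0) stop("degenerate input: points are collinear");
  }
  int i3 = -1;
  {
    V3 nrm = cross(H.pt(i1) - H.pt(i0), H.pt(i2) - H.pt(i0));
    nrm = nrm * (1.0 / std::max(norm(nrm), 1e-300));
    double d0 = dot(nrm, H.pt(i0)), best = H.eps;
    for (int i = 0; i < n; ++i) {
      double l = std::fabs(dot(nrm, H.pt(i)) - d0);
      if (l > best) { best = l; i3 = i; }
    }
    if (i3 < 0) stop("degenerate input: points are coplanar");
  }

  // four faces of the initial tetrahedron, oriented away from the centroid
  V3 cen = (H.pt(i0) + H.pt(i1) + H.pt(i2) + H.pt(i3)) * 0.25;
  int quad[4] = {i0, i1, i2, i3};
  static const int tet_faces[4][3] = {{0, 1, 2}, {0, 3, 1}, {0, 2, 3}, {1, 3, 2}};
  for (int f = 0; f < 4; ++f) {
    Face fc;
    fc.a = quad[tet_faces[f][0]];
    fc.b = quad[tet_faces[f][1]];
    fc.c = quad[tet_faces[f][2]];
    H.set_plane(fc);
    if (dot(fc.n, cen) - fc.d > 0) { std::swap(fc.b, fc.c); H.set_plane(fc); }
    H.faces.push_back(fc);
  }
  // neighbour wiring for the tetrahedron via an edge map
  {
    std::map<std::pair<int, int>, std::pair<int, int>> em;  // directed edge -> (face, slot)
    for (int fi = 0; fi < 4; ++fi) {
      int vs[3] = {H.faces[fi].a, H.faces[fi].b, H.faces[fi].c};
      for (int e = 0; e < 3; ++e)
        em[{vs[e], vs[(e + 1) % 3]}] = {fi, e};
    }
    for (auto& kv : em) {
      auto rev = em.find({kv.first.second, kv.first.first});
      H.faces[kv.second.first].nb[kv.second.second] = rev->second.first;
    }
  }

  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  H.distribute(all, {0, 1, 2, 3});

  std::vector<int> pending = {0, 1, 2, 3};
  std::vector<int> visible, horizon_face, horizon_slot;
  std::vector<char> visited;

  while (!pending.empty()) {
    int fi = pending.back();
    pending.pop_back();
    if (fi >= (int)H.faces.size()) continue;
    Face& f0 = H.faces[fi];
    if (!f0.alive || f0.outside.empty()) continue;
    int apex = f0.far_pt;

    // flood fill the set of faces visible from apex; collect horizon edges
    visible.clear(); horizon_face.clear(); horizon_slot.clear();
    visited.assign(H.faces.size(), 0);
    std::vector<int> stack = {fi};
    visited[fi] = 1;
    while (!stack.empty()) {
      int g = stack.back(); stack.pop_back();
      visible.push_back(g);
      for (int e = 0; e < 3; ++e) {
        int nb = H.faces[g].nb[e];
        if (visited[nb]) continue;
        if (H.dist(nb, apex) > H.eps) {
          visited[nb] = 1;
          stack.push_back(nb);
        } else {
          // horizon edge: edge e of face g, seen from the dead side
          horizon_face.push_back(g);
          horizon_slot.push_back(e);
        }
      }
    }

    // order horizon edges into a loop
    // edge e of face g runs between its e-th and (e+1)-th vertices
    std::map<int, int> next_start;  // start vertex -> index in horizon list
    std::vector<std::pair<int, int>> hedges(horizon_face.size());
    for (size_t h = 0; h < horizon_face.size(); ++h) {
      const Face& g = H.faces[horizon_face[h]];
      int vs[3] = {g.a, g.b, g.c};
      int s = vs[horizon_slot[h]], t = vs[(horizon_slot[h] + 1) % 3];
      hedges[h] = {s, t};
      next_start[s] = (int)h;
    }
    std::vector<int> order;
    order.reserve(hedges.size());
    int cur = 0;
    for (size_t h = 0; h < hedges.size(); ++h) {
      order.push_back(cur);
      auto it = next_start.find(hedges[cur].second);
      if (it == next_start.end()) stop("convex hull: open horizon (numerically degenerate input)");
      cur = it->second;
    }
    if (hedges[order.back()].second != hedges[order.front()].first)
      stop("convex hull: horizon is not a closed loop");

    // gather points to redistribute, kill visible faces
    std::vector<int> orphans;
    for (int g : visible) {
      Face& fg = H.faces[g];
      for (int p : fg.outside)
        if (p != apex) orphans.push_back(p);
      fg.outside.clear();
      fg.alive = false;
    }

    // build the new fan of faces apex + horizon edges
    std::vector<int> new_ids(order.size());
    for (size_t h = 0; h < order.size(); ++h) {
      Face nf;
      nf.a = hedges[order[h]].first;
      nf.b = hedges[order[h]].second;
      nf.c = apex;
      H.set_plane(nf);
      nf.nb[0] = H.faces[horizon_face[order[h]]].nb[horizon_slot[order[h]]];
      new_ids[h] = (int)H.faces.size();
      H.faces.push_back(nf);
    }
    for (size_t h = 0; h < order.size(); ++h) {
      Face& nf = H.faces[new_ids[h]];
      nf.nb[1] = new_ids[(h + 1) % order.size()];  // edge (b, apex)
      nf.nb[2] = new_ids[(h + order.size() - 1) % order.size()];  // edge (apex, a)
      // fix the outer neighbour's back-pointer
      Face& outer = H.faces[nf.nb[0]];
      int vs[3] = {outer.a, outer.b, outer.c};
      for (int e = 0; e < 3; ++e)
        if (vs[e] == nf.b && vs[(e + 1) % 3] == nf.a) outer.nb[e] = new_ids[h];
    }
    H.distribute(orphans, new_ids);
    for (int id : new_ids)
      if (!H.faces[id].outside.empty()) pending.push_back(id);
  }

  int nf = 0;
  for (const Face& f : H.faces) if (f.alive) ++nf;
  IntegerMatrix out(nf, 3);
  int r = 0;
  for (const Face& f : H.faces) {
    if (!f.alive) continue;
    out(r, 0) = f.a + 1; out(r, 1) = f.b + 1; out(r, 2) = f.c + 1;
    ++r;
  }
  return out;
}
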