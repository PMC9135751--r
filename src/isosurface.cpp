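#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Separable Gaussian smoothing of a 3D field stored in R's column-major
// (x fastest) order. sigma is in voxel units per axis; kernel truncated at
// 4 sigma and renormalised, with edge clamping (replicate padding).
// [[Rcpp::export(name = ".cpp_gaussian_smooth3d")]]
NumericVector cpp_gaussian_smooth3d(NumericVector field, IntegerVector dim,
                                    NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(field.begin(), field.end()), b(n);

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int radius = (int)std::ceil(4.0 * s);
    std::vector<double> k(2 * radius + 1);
    double sum = 0.0;
    for (int i = -radius; i <= radius; ++i) {
      k[i + radius] = std::exp(-0.5 * (i * i) / (s * s));
      sum += k[i + radius];
    }
    for (double& v : k) v /= sum;

    const int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
    const R_xlen_t stride = (axis == 0) ? 1
                          : (axis == 1) ? (R_xlen_t)nx
                          : (R_xlen_t)nx * ny;
    // iterate over all lines along `axis`
    for (int z = 0; z < (axis == 2 ? 1 : nz); ++z) {
      for (int y = 0; y < (axis == 1 ? 1 : ny); ++y) {
        for (int x = 0; x < (axis == 0 ? 1 : nx); ++x) {
          R_xlen_t base = (R_xlen_t)x + (R_xlen_t)nx * y + (R_xlen_t)nx * ny * z;
          for (int t = 0; t < len; ++t) {
            double acc = 0.0;
            for (int i = -radius; i <= radius; ++i) {
              int tt = t + i;
              if (tt < 0) tt = 0;
              if (tt >= len) tt = len - 1;
              acc += k[i + radius] * a[base + stride * tt];
            }
            b[base + stride * t] = acc;
          }
        }
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

namespace {

struct Key {
  uint64_t v;
  bool operator==(const Key& o) const { return v == o.v; }
};
struct KeyHash {
  size_t operator()(const Key& k) const {
    uint64_t x = k.v;
    x ^= x >> 33; x *= 0xff51afd7ed558ccdULL; x ^= x >> 33;
    x *= 0xc4ceb9fe1a85ec53ULL; x ^= x >> 33;
    return (size_t)x;
  }
};

struct MTState {
  const double* f;
  double level;
  int nx, ny, nz;
  double sx, sy, sz;
  std::unordered_map<Key, int, KeyHash> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;  // 0-based triples

  inline R_xlen_t gidx(int i, int j, int k) const {
    return (R_xlen_t)i + (R_xlen_t)nx * j + (R_xlen_t)nx * ny * k;
  }
  // vertex on the edge between grid nodes a and b (linear indices)
  int edge_point(R_xlen_t a, R_xlen_t b) {
    if (a > b) std::swap(a, b);
    Key key{(uint64_t)a * (uint64_t)(nx * (R_xlen_t)ny * nz) + (uint64_t)b};
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double fa = f[a], fb = f[b];
    double t = (level - fa) / (fb - fa);  // fa,fb straddle level by construction
    if (t < 0) t = 0; if (t > 1) t = 1;
    int ai = (int)(a % nx), aj = (int)((a / nx) % ny), ak = (int)(a / ((R_xlen_t)nx * ny));
    int bi = (int)(b % nx), bj = (int)((b / nx) % ny), bk = (int)(b / ((R_xlen_t)nx * ny));
    vx.push_back(sx * (ai + t * (bi - ai)));
    vy.push_back(sy * (aj + t * (bj - aj)));
    vz.push_back(sz * (ak + t * (bk - ak)));
    int id = (int)vx.size() - 1;
    edge_vertex.emplace(key, id);
    return id;
  }
  void emit(int a, int b, int c) {
    if (a == b || b == c || a == c) return;
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
  }
  // contour one tetrahedron given grid-node linear indices
  void do_tet(R_xlen_t p[4]) {
    int inside = 0, code = 0;
    for (int i = 0; i < 4; ++i)
      if (f[p[i]] > level) { inside++; code |= (1 << i); }
    if (inside == 0 || inside == 4) return;
    if (inside == 1 || inside == 3) {
      // single vertex separated from the other three
      int lone = -1;
      for (int i = 0; i < 4; ++i) {
        bool in = (code >> i) & 1;
        if ((inside == 1 && in) || (inside == 3 && !in)) { lone = i; break; }
      }
      int e[3], m = 0;
      for (int i = 0; i < 4; ++i)
        if (i != lone) e[m++] = edge_point(p[lone], p[i]);
      emit(e[0], e[1], e[2]);
    } else {
      // two inside / two outside: quad across 4 edges
      int in[2], out[2], mi = 0, mo = 0;
      for (int i = 0; i < 4; ++i)
        ((code >> i) & 1) ? (void)(in[mi++] = i) : (void)(out[mo++] = i);
      int e00 = edge_point(p[in[0]], p[out[0]]);
      int e01 = edge_point(p[in[0]], p[out[1]]);
      int e10 = edge_point(p[in[1]], p[out[0]]);
      int e11 = edge_point(p[in[1]], p[out[1]]);
      emit(e00, e01, e11);
      emit(e00, e11, e10);
    }
  }
};

}  // namespace

// Marching tetrahedra over a scalar field sampled at voxel centres
// (world coordinate = 0-based index * spacing). Each cell is split into the
// six Kuhn tetrahedra sharing the main diagonal, which is a conforming
// decomposition, so the extracted surface is watertight whenever the level
// set does not touch the grid boundary.
// [[Rcpp::export(name = ".cpp_marching_tetra")]]
List cpp_marching_tetra(NumericVector field, IntegerVector dim,
                        NumericVector spacing, double level) {
  MTState st;
  st.f = field.begin();
  st.level = level;
  st.nx = dim[0]; st.ny = dim[1]; st.nz = dim[2];
  st.sx = spacing[0]; st.sy = spacing[1]; st.sz = spacing[2];

  // paths from corner 0 to corner 7 of the unit cube; each defines one tet
  static const int paths[6][2] = {{1, 3}, {1, 5}, {2, 3}, {2, 6}, {4, 5}, {4, 6}};
  for (int k = 0; k + 1 < st.nz; ++k) {
    for (int j = 0; j + 1 < st.ny; ++j) {
      for (int i = 0; i + 1 < st.nx; ++i) {
        R_xlen_t c[8];
        for (int d = 0; d < 8; ++d)
          c[d] = st.gidx(i + (d & 1), j + ((d >> 1) & 1), k + ((d >> 2) & 1));
        // quick reject: all 8 on one side
        bool any_in = false, any_out = false;
        for (int d = 0; d < 8; ++d)
          (st.f[c[d]] > level) ? (any_in = true) : (any_out = true);
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          R_xlen_t p[4] = {c[0], c[paths[t][0]], c[paths[t][1]], c[7]};
          st.do_tet(p);
        }
      }
    }
  }

  const int nv = (int)st.vx.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i];
  }
  const int nt = (int)st.tri.size() / 3;
  IntegerMatrix F(nt, 3);
  for (int i = 0; i < nt; ++i) {
    F(i, 0) = st.tri[3 * i] + 1;  // 1-based for R
    F(i, 1) = st.tri[3 * i + 1] + 1;
    F(i, 2) = st.tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
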