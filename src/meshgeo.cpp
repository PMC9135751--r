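#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
#include <functional>

using namespace Rcpp;

namespace {

// Ericson, Real-Time Collision Detection: closest point on triangle (a,b,c) to p
inline void closest_on_tri(const double* p, const double* a, const double* b,
                           const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

}  // namespace

// Minimum Euclidean distance from each query point to a triangle soup,
// with the closest point itself. Brute force over faces with a bounding-sphere
// reject per triangle; fine for hull-sized face counts.
// [[Rcpp::export(name = ".cpp_closest_point_tris")]]
List cpp_closest_point_tris(NumericMatrix query, NumericMatrix V, IntegerMatrix F) {
  const int nq = query.nrow(), nf = F.nrow();
  // per-face centroid + bounding radius for cheap rejection
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  for (int f = 0; f < nf; ++f) {
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    cx[f] = (V(ia,0) + V(ib,0) + V(ic,0)) / 3.0;
    cy[f] = (V(ia,1) + V(ib,1) + V(ic,1)) / 3.0;
    cz[f] = (V(ia,2) + V(ib,2) + V(ic,2)) / 3.0;
    double r = 0;
    for (int v : {ia, ib, ic}) {
      double dx = V(v,0)-cx[f], dy = V(v,1)-cy[f], dz = V(v,2)-cz[f];
      r = std::max(r, dx*dx + dy*dy + dz*dz);
    }
    rad[f] = std::sqrt(r);
  }
  NumericVector dist(nq);
  NumericMatrix closest(nq, 3);
  for (int q = 0; q < nq; ++q) {
    double p[3] = {query(q,0), query(q,1), query(q,2)};
    double best = R_PosInf, bp[3] = {0, 0, 0};
    for (int f = 0; f < nf; ++f) {
      double dx = p[0]-cx[f], dy = p[1]-cy[f], dz = p[2]-cz[f];
      double dc = std::sqrt(dx*dx + dy*dy + dz*dz) - rad[f];
      if (dc * dc >= best && dc > 0) continue;
      int ia = F(f,0)-1, ib = F(f,1)-1, ic = F(f,2)-1;
      double a[3] = {V(ia,0), V(ia,1), V(ia,2)};
      double b[3] = {V(ib,0), V(ib,1), V(ib,2)};
      double c[3] = {V(ic,0), V(ic,1), V(ic,2)};
      double out[3];
      closest_on_tri(p, a, b, c, out);
      double d2 = 0;
      for (int i = 0; i < 3; ++i) d2 += (out[i]-p[i]) * (out[i]-p[i]);
      if (d2 < best) { best = d2; bp[0] = out[0]; bp[1] = out[1]; bp[2] = out[2]; }
    }
    dist[q] = std::sqrt(best);
    closest(q, 0) = bp[0]; closest(q, 1) = bp[1]; closest(q, 2) = bp[2];
  }
  return List::create(_["distance"] = dist, _["point"] = closest);
}

// Chord graph: connect every vertex to all vertices within `k` mesh edges,
// weighted by Euclidean (chord) length. k = 1 reproduces the plain edge graph.
// Returns a list with 1-based endpoints and weights.
// [[Rcpp::export(name = ".cpp_kring_edges")]]
List cpp_kring_edges(IntegerMatrix F, int nverts, int k, NumericMatrix V) {
  // adjacency from unique mesh edges
  std::vector<std::vector<int>> adj(nverts);
  {
    std::vector<std::pair<int,int>> E;
    E.reserve((size_t)F.nrow() * 3);
    for (int f = 0; f < F.nrow(); ++f) {
      int v[3] = {F(f,0)-1, F(f,1)-1, F(f,2)-1};
      for (int e = 0; e < 3; ++e) {
        int a = v[e], b = v[(e+1)%3];
        if (a > b) std::swap(a, b);
        E.emplace_back(a, b);
      }
    }
    std::sort(E.begin(), E.end());
    E.erase(std::unique(E.begin(), E.end()), E.end());
    for (auto& e : E) { adj[e.first].push_back(e.second); adj[e.second].push_back(e.first); }
  }
  std::vector<int> ei, ej;
  std::vector<double> w;
  std::vector<int> ring(nverts, -1), frontier, next;
  for (int s = 0; s < nverts; ++s) {
    ring[s] = s;  // marker: visited in this source's BFS
    frontier.assign(1, s);
    std::vector<int> reached;
    for (int depth = 0; depth < k; ++depth) {
      next.clear();
      for (int u : frontier)
        for (int v : adj[u])
          if (ring[v] != s) { ring[v] = s; next.push_back(v); reached.push_back(v); }
      frontier = next;
    }
    for (int v : reached) {
      if (v > s) {
        double dx = V(s,0)-V(v,0), dy = V(s,1)-V(v,1), dz = V(s,2)-V(v,2);
        ei.push_back(s + 1); ej.push_back(v + 1);
        w.push_back(std::sqrt(dx*dx + dy*dy + dz*dz));
      }
    }
  }
  return List::create(_["i"] = IntegerVector(ei.begin(), ei.end()),
                      _["j"] = IntegerVector(ej.begin(), ej.end()),
                      _["w"] = NumericVector(w.begin(), w.end()));
}

// For each source vertex, Dijkstra over the weighted graph with cutoff
// `radius`, summing `vertex_area` over all vertices whose shortest-path
// distance is <= radius (the source included). Returns the per-source sums.
// [[Rcpp::export(name = ".cpp_patch_areas")]]
NumericVector cpp_patch_areas(IntegerVector ei, IntegerVector ej, NumericVector w,
                              int nverts, NumericVector vertex_area,
                              double radius, IntegerVector sources) {
  std::vector<std::vector<std::pair<int,double>>> adj(nverts);
  for (int e = 0; e < ei.size(); ++e) {
    int a = ei[e] - 1, b = ej[e] - 1;
    adj[a].emplace_back(b, w[e]);
    adj[b].emplace_back(a, w[e]);
  }
  std::vector<double> dist(nverts, R_PosInf);
  std::vector<int> touched;
  NumericVector out(sources.size());
  typedef std::pair<double,int> QE;
  for (int si = 0; si < sources.size(); ++si) {
    int s = sources[si] - 1;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
    dist[s] = 0.0;
    touched.push_back(s);
    pq.push({0.0, s});
    double acc = 0.0;
    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      double d = top.first; int u = top.second;
      if (d > dist[u]) continue;
      acc += vertex_area[u];
      for (auto& nb : adj[u]) {
        double nd = d + nb.second;
        if (nd <= radius && nd < dist[nb.first]) {
          if (!std::isfinite(dist[nb.first])) touched.push_back(nb.first);
          dist[nb.first] = nd;
          pq.push({nd, nb.first});
        }
      }
    }
    out[si] = acc;
    for (int t : touched) dist[t] = R_PosInf;
    touched.clear();
  }
  return out;
}

// Full single-source shortest-path distances (no cutoff); used for the
// scale-equivariance checks and exposed for diagnostics.
// [[Rcpp::export(name = ".cpp_geodesic_dist")]]
NumericVector cpp_geodesic_dist(IntegerVector ei, IntegerVector ej, NumericVector w,
                                int nverts, int source) {
  std::vector<std::vector<std::pair<int,double>>> adj(nverts);
  for (int e = 0; e < ei.size(); ++e) {
    int a = ei[e] - 1, b = ej[e] - 1;
    adj[a].emplace_back(b, w[e]);
    adj[b].emplace_back(a, w[e]);
  }
  std::vector<double> dist(nverts, R_PosInf);
  typedef std::pair<double,int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  dist[source - 1] = 0.0;
  pq.push({0.0, source - 1});
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    if (top.first > dist[top.second]) continue;
    for (auto& nb : adj[top.second]) {
      double nd = top.first + nb.second;
      if (nd < dist[nb.first]) { dist[nb.first] = nd; pq.push({nd, nb.first}); }
    }
  }
  return NumericVector(dist.begin(), dist.end());
}

// Sum of sample areas within Euclidean `radius` of each centre; the hull-side
// patch area for the local gyrification index.
// [[Rcpp::export(name = ".cpp_radius_area")]]
NumericVector cpp_radius_area(NumericMatrix samples, NumericVector sample_area,
                              NumericMatrix centers, double radius) {
  const int ns = samples.nrow(), nc = centers.nrow();
  const double r2 = radius * radius;
  NumericVector out(nc);
  for (int c = 0; c < nc; ++c) {
    double px = centers(c,0), py = centers(c,1), pz = centers(c,2), acc = 0.0;
    for (int s = 0; s < ns; ++s) {
      double dx = samples(s,0)-px, dy = samples(s,1)-py, dz = samples(s,2)-pz;
      if (dx*dx + dy*dy + dz*dz <= r2) acc += sample_area[s];
    }
    out[c] = acc;
  }
  return out;
}

// Connected components over mesh vertices via shared edges (union-find);
// returns 1-based component labels, largest component relabelled 1.
// [[Rcpp::export(name = ".cpp_mesh_components")]]
IntegerVector cpp_mesh_components(IntegerMatrix F, int nverts) {
  std::vector<int> parent(nverts);
  for (int i = 0; i < nverts; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int f = 0; f < F.nrow(); ++f) {
    int a = find(F(f,0)-1), b = find(F(f,1)-1), c = find(F(f,2)-1);
    parent[b] = a;
    parent[find(c)] = find(a);
  }
  std::vector<int> count(nverts, 0);
  for (int i = 0; i < nverts; ++i) count[find(i)]++;
  // order component roots by decreasing size
  std::vector<int> roots;
  for (int i = 0; i < nverts; ++i) if (count[i] > 0) roots.push_back(i);
  std::sort(roots.begin(), roots.end(),
            [&](int a, int b) { return count[a] > count[b]; });
  std::vector<int> label(nverts, 0);
  for (size_t r = 0; r < roots.size(); ++r) label[roots[r]] = (int)r + 1;
  IntegerVector out(nverts);
  for (int i = 0; i < nverts; ++i) out[i] = label[find(i)];
  return out;
}

// Nearest non-zero label for each query point (world mm), searching the label
// grid in expanding Chebyshev shells around the point's voxel. Distances are
// Euclidean in mm; ties broken by the smallest label id.
// [[Rcpp::export(name = ".cpp_nearest_label")]]
IntegerVector cpp_nearest_label(NumericMatrix query, IntegerVector labels,
                                IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double minsp = std::min({sx, sy, sz});
  const int max_shell = std::max({nx, ny, nz});
  IntegerVector out(query.nrow());
  for (int q = 0; q < query.nrow(); ++q) {
    double px = query(q,0), py = query(q,1), pz = query(q,2);
    int ci = (int)std::lround(px / sx), cj = (int)std::lround(py / sy),
        ck = (int)std::lround(pz / sz);
    double best = R_PosInf;
    int best_lab = NA_INTEGER;
    for (int s = 0; s <= max_shell; ++s) {
      if (best < R_PosInf && (s - 1) * minsp > best) break;
      int i0 = ci - s, i1 = ci + s, j0 = cj - s, j1 = cj + s, k0 = ck - s, k1 = ck + s;
      for (int k = std::max(0, k0); k <= std::min(nz - 1, k1); ++k) {
        for (int j = std::max(0, j0); j <= std::min(ny - 1, j1); ++j) {
          bool j_edge = (j == j0 || j == j1), k_edge = (k == k0 || k == k1);
          int istep = (j_edge || k_edge) ? 1 : (i1 - i0 > 0 ? i1 - i0 : 1);
          for (int i = std::max(0, i0); i <= std::min(nx - 1, i1); i += istep) {
            if (!j_edge && !k_edge && i != i0 && i != i1) continue;
            int lab = labels[(R_xlen_t)i + (R_xlen_t)nx * j + (R_xlen_t)nx * ny * k];
            if (lab == 0) continue;
            double dx = i * sx - px, dy = j * sy - py, dz = k * sz - pz;
            double d = std::sqrt(dx*dx + dy*dy + dz*dz);
            if (d < best - 1e-12 || (std::fabs(d - best) <= 1e-12 && lab < best_lab)) {
              best = d; best_lab = lab;
            }
          }
        }
      }
    }
    out[q] = best_lab;
  }
  return out;
}

// Taubin lambda/mu smoothing with uniform weights over the unique mesh edges.
// [[Rcpp::export(name = ".cpp_taubin_smooth")]]
NumericMatrix cpp_taubin_smooth(NumericMatrix V0, IntegerMatrix F,
                                int iterations, double lambda, double mu) {
  const int n = V0.nrow();
  std::vector<std::pair<int,int>> E;
  E.reserve((size_t)F.nrow() * 3);
  for (int f = 0; f < F.nrow(); ++f) {
    int v[3] = {F(f,0)-1, F(f,1)-1, F(f,2)-1};
    for (int e = 0; e < 3; ++e) {
      int a = v[e], b = v[(e+1)%3];
      if (a > b) std::swap(a, b);
      E.emplace_back(a, b);
    }
  }
  std::sort(E.begin(), E.end());
  E.erase(std::unique(E.begin(), E.end()), E.end());
  std::vector<int> deg(n, 0);
  for (auto& e : E) { deg[e.first]++; deg[e.second]++; }
  std::vector<double> X(n), Y(n), Z(n), ax(n), ay(n), az(n);
  for (int i = 0; i < n; ++i) { X[i] = V0(i,0); Y[i] = V0(i,1); Z[i] = V0(i,2); }
  for (int it = 0; it < iterations; ++it) {
    for (double step : {lambda, mu}) {
      std::fill(ax.begin(), ax.end(), 0.0);
      std::fill(ay.begin(), ay.end(), 0.0);
      std::fill(az.begin(), az.end(), 0.0);
      for (auto& e : E) {
        ax[e.first] += X[e.second]; ax[e.second] += X[e.first];
        ay[e.first] += Y[e.second]; ay[e.second] += Y[e.first];
        az[e.first] += Z[e.second]; az[e.second] += Z[e.first];
      }
      for (int i = 0; i < n; ++i) {
        if (deg[i] == 0) continue;
        X[i] += step * (ax[i] / deg[i] - X[i]);
        Y[i] += step * (ay[i] / deg[i] - Y[i]);
        Z[i] += step * (az[i] / deg[i] - Z[i]);
      }
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i,0) = X[i]; out(i,1) = Y[i]; out(i,2) = Z[i]; }
  return out;
}
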