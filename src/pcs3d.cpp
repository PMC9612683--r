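// Voxel-level primitives: slice-wise region growing with inter-slice
// overlap propagation, 3-D connected components, anisotropic Euclidean
// distance transform, separable Gaussian smoothing, isosurface extraction
// (crack-free marching tetrahedra on the voxel-center lattice) and Taubin
// mesh smoothing.

#include <Rcpp.h>
#include <array>
#include <cmath>
#include <cstdint>
#include <deque>
#include <limits>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Arrays follow R column-major layout with dim = (nz, ny, nx):
// linear index v = i + nz * (j + ny * k), 0-based.

static inline R_xlen_t lin(int i, int j, int k, int nz, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nz * ((R_xlen_t)j + (R_xlen_t)ny * k);
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, sigma in voxel units (same along every axis).
// Truncated at 3.5 sigma; the kernel is renormalised at the borders.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dim,
                                double sigma) {
  if (sigma <= 0) return clone(vol);
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const int radius = std::max(1, (int)std::ceil(3.5 * sigma));
  std::vector<double> kern(2 * radius + 1);
  for (int t = -radius; t <= radius; ++t)
    kern[t + radius] = std::exp(-0.5 * (double)t * t / (sigma * sigma));

  NumericVector cur = clone(vol);
  NumericVector nxt(vol.size());
  const R_xlen_t strides[3] = {1, (R_xlen_t)n0, (R_xlen_t)n0 * n1};
  const int lens[3] = {n0, n1, n2};

  for (int ax = 0; ax < 3; ++ax) {
    const R_xlen_t S = strides[ax];
    const int L = lens[ax];
    // iterate over all lines along axis `ax`
    const int oa = (ax == 0) ? 1 : 0;
    const int ob = (ax == 2) ? 1 : 2;
    const R_xlen_t Sa = strides[oa], Sb = strides[ob];
    const int La = lens[oa], Lb = lens[ob];
    for (int b = 0; b < Lb; ++b) {
      for (int a = 0; a < La; ++a) {
        const R_xlen_t base = (R_xlen_t)a * Sa + (R_xlen_t)b * Sb;
        for (int p = 0; p < L; ++p) {
          double acc = 0.0, wsum = 0.0;
          const int t0 = std::max(-radius, -p);
          const int t1 = std::min(radius, L - 1 - p);
          for (int t = t0; t <= t1; ++t) {
            const double w = kern[t + radius];
            acc += w * cur[base + (R_xlen_t)(p + t) * S];
            wsum += w;
          }
          nxt[base + (R_xlen_t)p * S] = acc / wsum;
        }
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}

// ---------------------------------------------------------------------------
// Squared-distance transform along one axis (Felzenszwalb & Huttenlocher),
// with physical sample spacing s.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  int kq = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double sq = (double)q * s;
    while (true) {
      double sv = (double)v[kq] * s;
      double num = (f[q] + sq * sq) - (f[v[kq]] + sv * sv);
      double den = 2.0 * sq - 2.0 * sv;
      double inter = num / den;
      if (inter <= z[kq]) {
        --kq;
      } else {
        ++kq;
        v[kq] = q;
        z[kq] = inter;
        z[kq + 1] = INF;
        break;
      }
    }
  }
  kq = 0;
  for (int q = 0; q < n; ++q) {
    double sq = (double)q * s;
    while (z[kq + 1] < sq) ++kq;
    double sv = (double)v[kq] * s;
    d[q] = (sq - sv) * (sq - sv) + f[v[kq]];
  }
}

// Euclidean distance (mm) from every foreground voxel to the nearest
// background voxel centre. Background voxels get 0.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector fg, IntegerVector dim,
                      NumericVector spacing) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  // large finite sentinel: true infinity breaks the parabola intersection
  // arithmetic (inf - inf = NaN) when two unreached samples meet
  const double BIG = 1e20;
  R_xlen_t n = fg.size();
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = fg[i] ? BIG : 0.0;

  const R_xlen_t strides[3] = {1, (R_xlen_t)n0, (R_xlen_t)n0 * n1};
  const int lens[3] = {n0, n1, n2};
  const int maxlen = std::max(n0, std::max(n1, n2));
  std::vector<double> f(maxlen), out(maxlen), z(maxlen + 1);
  std::vector<int> v(maxlen);

  for (int ax = 0; ax < 3; ++ax) {
    const R_xlen_t S = strides[ax];
    const int L = lens[ax];
    const double s = spacing[ax];
    const int oa = (ax == 0) ? 1 : 0;
    const int ob = (ax == 2) ? 1 : 2;
    const R_xlen_t Sa = strides[oa], Sb = strides[ob];
    const int La = lens[oa], Lb = lens[ob];
    for (int b = 0; b < Lb; ++b) {
      for (int a = 0; a < La; ++a) {
        const R_xlen_t base = (R_xlen_t)a * Sa + (R_xlen_t)b * Sb;
        bool allbig = true;
        for (int p = 0; p < L; ++p) {
          f[p] = d[base + (R_xlen_t)p * S];
          if (f[p] < BIG) allbig = false;
        }
        if (allbig) continue;  // line stays unreached
        dt1d(f, out, v, z, L, s);
        for (int p = 0; p < L; ++p) d[base + (R_xlen_t)p * S] = out[p];
      }
    }
  }
  NumericVector res(n);
  for (R_xlen_t i = 0; i < n; ++i)
    res[i] = (d[i] >= 1e19) ? R_PosInf : std::sqrt(d[i]);
  return res;
}

// ---------------------------------------------------------------------------
// Connected-component labelling, connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int conn) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<std::array<int, 3>> offs;
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj)
      for (int dk = -1; dk <= 1; ++dk) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (conn == 6 && manh != 1) continue;
        offs.push_back({di, dj, dk});
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < nx; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nz; ++i) {
        R_xlen_t v = lin(i, j, k, nz, ny);
        if (!mask[v] || lab[v]) continue;
        lab[v] = ++next;
        stack.clear();
        stack.push_back(v);
        while (!stack.empty()) {
          R_xlen_t u = stack.back();
          stack.pop_back();
          int ui = (int)(u % nz);
          int uj = (int)((u / nz) % ny);
          int uk = (int)(u / ((R_xlen_t)nz * ny));
          for (auto &o : offs) {
            int a = ui + o[0], b = uj + o[1], c = uk + o[2];
            if (a < 0 || a >= nz || b < 0 || b >= ny || c < 0 || c >= nx)
              continue;
            R_xlen_t w = lin(a, b, c, nz, ny);
            if (mask[w] && !lab[w]) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Slice-wise region growing. Within each axial slice (fixed k? no: fixed
// FIRST axis index i = slice) an 8-connected flood fill accepts voxels whose
// integer-rounded HU lies in [lo, hi]; the area segmented on a slice seeds
// its two neighbours by direct (j, k) overlap, iterated to a fixed point.
// Seed voxels are always part of the mask and always act as flood sources.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector hu, IntegerVector dim,
                              IntegerVector seeds, double lo, double hi) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t nvox = hu.size();
  std::vector<char> band(nvox);
  for (R_xlen_t v = 0; v < nvox; ++v) {
    double r = std::nearbyint(hu[v]);
    band[v] = (r >= lo && r <= hi) ? 1 : 0;
  }
  std::vector<char> mask(nvox, 0);
  std::vector<std::vector<R_xlen_t>> seeds_by_slice(nz);
  for (R_xlen_t s = 0; s < seeds.size(); ++s) {
    R_xlen_t v = seeds[s];
    int i = (int)(v % nz);
    seeds_by_slice[i].push_back(v);
  }

  std::deque<int> q;
  std::vector<char> inq(nz, 0);
  for (int i = 0; i < nz; ++i)
    if (!seeds_by_slice[i].empty()) {
      q.push_back(i);
      inq[i] = 1;
    }

  const int dj8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dk8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::vector<R_xlen_t> stack;

  while (!q.empty()) {
    int i = q.front();
    q.pop_front();
    inq[i] = 0;
    bool grew = false;
    stack.clear();
    // footprint seeds on this slice: always included, always sources
    for (R_xlen_t v : seeds_by_slice[i]) {
      if (!mask[v]) {
        mask[v] = 1;
        grew = true;
      }
      stack.push_back(v);
    }
    // overlap projection from adjacent slices
    for (int k = 0; k < nx; ++k)
      for (int j = 0; j < ny; ++j) {
        R_xlen_t v = lin(i, j, k, nz, ny);
        if (mask[v] || !band[v]) continue;
        bool from_nb = (i > 0 && mask[v - 1]) || (i < nz - 1 && mask[v + 1]);
        if (from_nb) {
          mask[v] = 1;
          grew = true;
          stack.push_back(v);
        }
      }
    // in-slice 8-connected flood fill
    while (!stack.empty()) {
      R_xlen_t u = stack.back();
      stack.pop_back();
      int uj = (int)((u / nz) % ny);
      int uk = (int)(u / ((R_xlen_t)nz * ny));
      for (int t = 0; t < 8; ++t) {
        int b = uj + dj8[t], c = uk + dk8[t];
        if (b < 0 || b >= ny || c < 0 || c >= nx) continue;
        R_xlen_t w = lin(i, b, c, nz, ny);
        if (!mask[w] && band[w]) {
          mask[w] = 1;
          grew = true;
          stack.push_back(w);
        }
      }
    }
    if (grew) {
      if (i > 0 && !inq[i - 1]) {
        q.push_back(i - 1);
        inq[i - 1] = 1;
      }
      if (i < nz - 1 && !inq[i + 1]) {
        q.push_back(i + 1);
        inq[i + 1] = 1;
      }
    }
  }
  LogicalVector res(nvox);
  for (R_xlen_t v = 0; v < nvox; ++v) res[v] = mask[v] != 0;
  return res;
}

// ---------------------------------------------------------------------------
// Isosurface extraction: marching tetrahedra on the voxel-centre lattice.
// Each lattice cube is split into 5 tetrahedra; the two mirror-image
// decompositions alternate in a checkerboard so that face diagonals agree
// between neighbouring cubes (crack-free, watertight for interior surfaces).
// A voxel is "inside" iff field > level. Vertices are deduplicated on
// lattice edges, coordinates are physical mm, faces wind outward.

static const int TETS_EVEN[5][4] = {
    {0, 1, 2, 4}, {3, 1, 2, 7}, {5, 1, 4, 7}, {6, 2, 4, 7}, {1, 2, 4, 7}};
static const int TETS_ODD[5][4] = {
    {1, 0, 3, 5}, {2, 0, 3, 6}, {4, 0, 5, 6}, {7, 3, 5, 6}, {0, 3, 5, 6}};

// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dim, double level,
                    NumericVector spacing, NumericVector origin) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const double oz = origin[0], oy = origin[1], ox = origin[2];

  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> VX, VY, VZ;
  std::vector<std::array<int, 3>> faces;

  auto node_world = [&](R_xlen_t node, double *w) {
    int i = (int)(node % nz);
    int j = (int)((node / nz) % ny);
    int k = (int)(node / ((R_xlen_t)nz * ny));
    w[0] = ox + k * dx;  // x
    w[1] = oy + j * dy;  // y
    w[2] = oz + i * dz;  // z
  };

  auto edge_vertex = [&](R_xlen_t a, R_xlen_t b) -> int {
    if (a > b) std::swap(a, b);
    uint64_t key = (uint64_t)a * (uint64_t)field.size() + (uint64_t)b;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double fa = field[a], fb = field[b];
    double t = (level - fa) / (fb - fa);
    if (t < 1e-4) t = 1e-4;
    if (t > 1.0 - 1e-4) t = 1.0 - 1e-4;
    double wa[3], wb[3];
    node_world(a, wa);
    node_world(b, wb);
    int id = (int)VX.size();
    VX.push_back(wa[0] + t * (wb[0] - wa[0]));
    VY.push_back(wa[1] + t * (wb[1] - wa[1]));
    VZ.push_back(wa[2] + t * (wb[2] - wa[2]));
    vmap.emplace(key, id);
    return id;
  };

  // emit a triangle oriented away from the inside reference point
  auto emit = [&](int v0, int v1, int v2, const double *inside_pt) {
    double p0[3] = {VX[v0], VY[v0], VZ[v0]};
    double p1[3] = {VX[v1], VY[v1], VZ[v1]};
    double p2[3] = {VX[v2], VY[v2], VZ[v2]};
    double e1[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
    double e2[3] = {p2[0] - p0[0], p2[1] - p0[1], p2[2] - p0[2]};
    double nrm[3] = {e1[1] * e2[2] - e1[2] * e2[1],
                     e1[2] * e2[0] - e1[0] * e2[2],
                     e1[0] * e2[1] - e1[1] * e2[0]};
    double c[3] = {(p0[0] + p1[0] + p2[0]) / 3.0 - inside_pt[0],
                   (p0[1] + p1[1] + p2[1]) / 3.0 - inside_pt[1],
                   (p0[2] + p1[2] + p2[2]) / 3.0 - inside_pt[2]};
    double d = nrm[0] * c[0] + nrm[1] * c[1] + nrm[2] * c[2];
    if (d >= 0)
      faces.push_back({v0, v1, v2});
    else
      faces.push_back({v0, v2, v1});
  };

  R_xlen_t corner[8];
  double w[3];
  for (int k = 0; k < nx - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nz - 1; ++i) {
        for (int c = 0; c < 8; ++c)
          corner[c] = lin(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1),
                          nz, ny);
        // quick reject
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          if (field[corner[c]] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        const int(*tets)[4] =
            (((i + j + k) & 1) == 0) ? TETS_EVEN : TETS_ODD;
        for (int t = 0; t < 5; ++t) {
          R_xlen_t nd[4];
          bool in[4];
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            nd[c] = corner[tets[t][c]];
            in[c] = field[nd[c]] > level;
            if (in[c]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          // reference interior point = mean of inside corners
          double ip[3] = {0, 0, 0};
          int cnt = 0;
          for (int c = 0; c < 4; ++c)
            if (in[c]) {
              node_world(nd[c], w);
              ip[0] += w[0];
              ip[1] += w[1];
              ip[2] += w[2];
              ++cnt;
            }
          ip[0] /= cnt;
          ip[1] /= cnt;
          ip[2] /= cnt;
          int iv[4], ov[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c)
            (in[c] ? iv[ni++] : ov[no++]) = c;
          if (nin == 1) {
            int a = edge_vertex(nd[iv[0]], nd[ov[0]]);
            int b = edge_vertex(nd[iv[0]], nd[ov[1]]);
            int cc = edge_vertex(nd[iv[0]], nd[ov[2]]);
            emit(a, b, cc, ip);
          } else if (nin == 3) {
            int a = edge_vertex(nd[ov[0]], nd[iv[0]]);
            int b = edge_vertex(nd[ov[0]], nd[iv[1]]);
            int cc = edge_vertex(nd[ov[0]], nd[iv[2]]);
            emit(a, b, cc, ip);
          } else {
            // 2 in, 2 out: quad on 4 edges
            int a = edge_vertex(nd[iv[0]], nd[ov[0]]);
            int b = edge_vertex(nd[iv[0]], nd[ov[1]]);
            int cc = edge_vertex(nd[iv[1]], nd[ov[1]]);
            int dd = edge_vertex(nd[iv[1]], nd[ov[0]]);
            emit(a, b, cc, ip);
            emit(a, cc, dd, ip);
          }
        }
      }

  int nV = (int)VX.size(), nF = (int)faces.size();
  NumericMatrix V(nV, 3);
  for (int v = 0; v < nV; ++v) {
    V(v, 0) = VX[v];
    V(v, 1) = VY[v];
    V(v, 2) = VZ[v];
  }
  IntegerMatrix F(nF, 3);
  for (int f = 0; f < nF; ++f) {
    F(f, 0) = faces[f][0] + 1;
    F(f, 1) = faces[f][1] + 1;
    F(f, 2) = faces[f][2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Taubin lambda|mu smoothing. Uniform (umbrella) weights.
// [[Rcpp::export]]
NumericMatrix cpp_taubin(NumericMatrix V, IntegerMatrix F, int iterations,
                         double lambda, double mu) {
  const int nV = V.nrow(), nF = F.nrow();
  // adjacency from unique undirected edges
  std::vector<std::vector<int>> adj(nV);
  {
    std::unordered_map<uint64_t, char> seen;
    seen.reserve((size_t)nF * 3);
    auto addEdge = [&](int a, int b) {
      int lo = std::min(a, b), hi = std::max(a, b);
      uint64_t key = (uint64_t)lo * (uint64_t)nV + (uint64_t)hi;
      if (seen.emplace(key, 1).second) {
        adj[lo].push_back(hi);
        adj[hi].push_back(lo);
      }
    };
    for (int f = 0; f < nF; ++f) {
      int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
      addEdge(a, b);
      addEdge(b, c);
      addEdge(c, a);
    }
  }
  NumericMatrix cur = clone(V);
  NumericMatrix nxt(nV, 3);
  auto step = [&](double factor) {
    for (int v = 0; v < nV; ++v) {
      const std::vector<int> &nb = adj[v];
      if (nb.empty()) {
        nxt(v, 0) = cur(v, 0);
        nxt(v, 1) = cur(v, 1);
        nxt(v, 2) = cur(v, 2);
        continue;
      }
      double mx = 0, my = 0, mz = 0;
      for (int u : nb) {
        mx += cur(u, 0);
        my += cur(u, 1);
        mz += cur(u, 2);
      }
      double inv = 1.0 / nb.size();
      nxt(v, 0) = cur(v, 0) + factor * (mx * inv - cur(v, 0));
      nxt(v, 1) = cur(v, 1) + factor * (my * inv - cur(v, 1));
      nxt(v, 2) = cur(v, 2) + factor * (mz * inv - cur(v, 2));
    }
    std::swap(cur, nxt);
  };
  for (int it = 0; it < iterations; ++it) {
    step(lambda);
    step(mu);
  }
  return cur;
}
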