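// Core computational geometry and persistence machinery.
//
// Three pieces live here:
//   1. a persistence reduction over an arbitrary filtered simplicial complex
//      (standard boundary-matrix reduction over GF(2) with the twist/clearing
//      optimisation, high dimensions first);
//   2. the Vietoris-Rips clique filtration of a 3D point cloud (simplices up
//      to dimension 3, filtration value = largest pairwise distance);
//   3. an incremental 3D Delaunay triangulation (Bowyer-Watson with an
//      infinite vertex) and the Alpha filtration derived from it
//      (squared-circumradius values with Gabriel propagation).
//
// Predicates use long double accumulation; configurations too close to
// degeneracy raise a flag so the caller can retry on perturbed input.

#include <Rcpp.h>
#include <array>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

typedef long double ld;

// ---------------------------------------------------------------------------
// Filtration container + persistence reduction
// ---------------------------------------------------------------------------

struct Filtration {
  // simplices with sorted vertex ids, -1 padding; dim in 0..3
  std::vector<std::array<int, 4>> verts;
  std::vector<double> value;
  std::vector<int> dim;
  int n_vertices = 0;

  void add(std::array<int, 4> v, int d, double val) {
    std::sort(v.begin(), v.begin() + d + 1);
    for (int i = d + 1; i < 4; ++i) v[i] = -1;
    verts.push_back(v);
    value.push_back(val);
    dim.push_back(d);
  }
  size_t size() const { return verts.size(); }
};

static inline uint64_t simplex_key(const std::array<int, 4>& v, uint64_t base) {
  uint64_t k = 0;
  for (int i = 0; i < 4; ++i) k = k * base + (uint64_t)(v[i] + 1);
  return k;
}

// symmetric difference of two sorted int vectors, result into out
static void sym_diff(std::vector<int>& a, const std::vector<int>& b,
                     std::vector<int>& out) {
  out.clear();
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) out.push_back(a[i++]);
    else if (b[j] < a[i]) out.push_back(b[j++]);
    else { ++i; ++j; }
  }
  while (i < a.size()) out.push_back(a[i++]);
  while (j < b.size()) out.push_back(b[j++]);
}

// Reduce the filtration; return (dim, birth, death) with death = Inf for
// essential classes, for dims 0..max_hom_dim.
static NumericMatrix reduce_filtration(Filtration& F, int max_hom_dim) {
  const size_t m = F.size();
  const uint64_t base = (uint64_t)F.n_vertices + 2;

  // filtration order: (value, dim, lex vertices)
  std::vector<int> ord(m);
  for (size_t i = 0; i < m; ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (F.value[a] != F.value[b]) return F.value[a] < F.value[b];
    if (F.dim[a] != F.dim[b]) return F.dim[a] < F.dim[b];
    return F.verts[a] < F.verts[b];
  });
  // rank of each simplex in filtration order
  std::vector<int> rank(m);
  for (size_t i = 0; i < m; ++i) rank[ord[i]] = (int)i;

  // key -> filtration rank, for facet lookup (sorted array + binary search)
  std::vector<std::pair<uint64_t, int>> keymap(m);
  for (size_t i = 0; i < m; ++i)
    keymap[i] = { simplex_key(F.verts[i], base), rank[i] };
  std::sort(keymap.begin(), keymap.end());
  auto lookup = [&](const std::array<int, 4>& v) -> int {
    uint64_t k = simplex_key(v, base);
    auto it = std::lower_bound(keymap.begin(), keymap.end(),
                               std::make_pair(k, -1));
    if (it == keymap.end() || it->first != k)
      stop("internal error: facet not found in filtration");
    return it->second;
  };

  int maxd = 0;
  for (size_t i = 0; i < m; ++i) maxd = std::max(maxd, F.dim[i]);

  std::vector<char> cleared(m, 0);        // killed births (skip their columns)
  std::vector<char> is_death(m, 0);
  std::vector<int> pivot_of(m, -1);       // pivot rank -> column rank
  std::vector<std::vector<int>> colstore(m);
  std::vector<std::pair<int, int>> pairs; // (birth rank, death rank)

  std::vector<int> col, tmp;
  for (int d = maxd; d >= 1; --d) {
    for (size_t r = 0; r < m; ++r) {
      int s = ord[r];
      if (F.dim[s] != d || cleared[r]) continue;
      // boundary column: ranks of facets
      col.clear();
      std::array<int, 4> fv;
      for (int drop = 0; drop <= d; ++drop) {
        int k = 0;
        for (int i = 0; i <= d; ++i)
          if (i != drop) fv[k++] = F.verts[s][i];
        for (; k < 4; ++k) fv[k] = -1;
        col.push_back(lookup(fv));
      }
      std::sort(col.begin(), col.end());
      while (!col.empty()) {
        int low = col.back();
        int k = pivot_of[low];
        if (k < 0) break;
        sym_diff(col, colstore[k], tmp);
        col.swap(tmp);
      }
      if (!col.empty()) {
        int low = col.back();
        pivot_of[low] = (int)r;
        colstore[r] = col;
        pairs.push_back({ low, (int)r });
        cleared[low] = 1;
        is_death[r] = 1;
      }
    }
  }

  // bars
  std::vector<double> bdim, bbirth, bdeath;
  for (auto& pr : pairs) {
    int bi = ord[pr.first], di = ord[pr.second];
    if (F.dim[bi] > max_hom_dim) continue;
    bdim.push_back(F.dim[bi]);
    bbirth.push_back(F.value[bi]);
    bdeath.push_back(F.value[di]);
  }
  for (size_t r = 0; r < m; ++r) {
    int s = ord[r];
    if (F.dim[s] > max_hom_dim) continue;
    if (!cleared[r] && !is_death[r]) {
      bdim.push_back(F.dim[s]);
      bbirth.push_back(F.value[s]);
      bdeath.push_back(R_PosInf);
    }
  }
  NumericMatrix out(bdim.size(), 3);
  for (size_t i = 0; i < bdim.size(); ++i) {
    out(i, 0) = bdim[i];
    out(i, 1) = bbirth[i];
    out(i, 2) = bdeath[i];
  }
  colnames(out) = CharacterVector::create("dim", "birth", "death");
  return out;
}

// ---------------------------------------------------------------------------
// Vietoris-Rips clique filtration
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_vr_pairs(NumericMatrix X, double rf, int max_hom_dim) {
  const int n = X.nrow();
  if (n < 1) stop("empty point cloud");
  if (n > 5000) stop("point cloud too large for the VR engine");
  if (max_hom_dim < 0 || max_hom_dim > 2) stop("max_hom_dim must be 0, 1 or 2");

  std::vector<std::array<double, 3>> p(n);
  for (int i = 0; i < n; ++i) p[i] = { X(i, 0), X(i, 1), X(i, 2) };
  // pairwise distances
  std::vector<double> D((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = p[i][0] - p[j][0], dy = p[i][1] - p[j][1],
             dz = p[i][2] - p[j][2];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      D[(size_t)i * n + j] = D[(size_t)j * n + i] = d;
    }
  auto dist = [&](int i, int j) { return D[(size_t)i * n + j]; };

  Filtration F;
  F.n_vertices = n;
  for (int i = 0; i < n; ++i) F.add({ i, -1, -1, -1 }, 0, 0.0);

  // higher-neighbour adjacency within rf
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (dist(i, j) <= rf) nb[i].push_back(j);

  for (int i = 0; i < n; ++i)
    for (int j : nb[i])
      F.add({ i, j, -1, -1 }, 1, dist(i, j));

  const size_t simplex_cap = 40000000;
  if (max_hom_dim >= 1) {
    std::vector<int> common;
    for (int i = 0; i < n; ++i) {
      for (size_t a = 0; a < nb[i].size(); ++a) {
        int j = nb[i][a];
        // common higher neighbours of i and j
        common.clear();
        std::set_intersection(nb[i].begin(), nb[i].end(),
                              nb[j].begin(), nb[j].end(),
                              std::back_inserter(common));
        for (int k : common) {
          double v = std::max({ dist(i, j), dist(i, k), dist(j, k) });
          F.add({ i, j, k, -1 }, 2, v);
          if (max_hom_dim >= 2) {
            for (int l : common) {
              if (l <= k) continue;
              if (dist(k, l) > rf) continue;
              double w = std::max({ v, dist(i, l), dist(j, l), dist(k, l) });
              F.add({ i, j, k, l }, 3, w);
            }
          }
          if (F.size() > simplex_cap)
            stop("VR filtration exceeds the simplex budget; reduce r_f");
        }
      }
    }
  }
  return reduce_filtration(F, max_hom_dim);
}

// ---------------------------------------------------------------------------
// Geometric predicates (long double)
// ---------------------------------------------------------------------------

static inline ld det3(ld a, ld b, ld c, ld d, ld e, ld f, ld g, ld h, ld i) {
  return a * (e * i - f * h) - b * (d * i - f * g) + c * (d * h - e * g);
}

// magnitude bound: same expression with every product taken in absolute value
static inline ld det3_mag(ld a, ld b, ld c, ld d, ld e, ld f, ld g, ld h,
                          ld i) {
  a = std::fabs((double)a); b = std::fabs((double)b); c = std::fabs((double)c);
  d = std::fabs((double)d); e = std::fabs((double)e); f = std::fabs((double)f);
  g = std::fabs((double)g); h = std::fabs((double)h); i = std::fabs((double)i);
  return a * (e * i + f * h) + b * (d * i + f * g) + c * (d * h + e * g);
}

// > 0 iff d lies on the positive side of oriented plane (a,b,c);
// mag receives a bound on the summed term magnitudes for error control
static ld orient3d_m(const double* a, const double* b, const double* c,
                     const double* d, ld* mag) {
  ld r[9] = { (ld)a[0] - d[0], (ld)a[1] - d[1], (ld)a[2] - d[2],
              (ld)b[0] - d[0], (ld)b[1] - d[1], (ld)b[2] - d[2],
              (ld)c[0] - d[0], (ld)c[1] - d[1], (ld)c[2] - d[2] };
  if (mag)
    *mag = det3_mag(r[0], r[1], r[2], r[3], r[4], r[5], r[6], r[7], r[8]);
  return det3(r[0], r[1], r[2], r[3], r[4], r[5], r[6], r[7], r[8]);
}

static ld orient3d(const double* a, const double* b, const double* c,
                   const double* d) {
  return orient3d_m(a, b, c, d, nullptr);
}

// sign s.t. for orient3d(a,b,c,d) > 0, e strictly inside the circumsphere of
// (a,b,c,d) gives insphere > 0
static ld insphere_m(const double* a, const double* b, const double* c,
                     const double* d, const double* e, ld* mag) {
  ld ax = a[0] - e[0], ay = a[1] - e[1], az = a[2] - e[2];
  ld bx = b[0] - e[0], by = b[1] - e[1], bz = b[2] - e[2];
  ld cx = c[0] - e[0], cy = c[1] - e[1], cz = c[2] - e[2];
  ld dx = d[0] - e[0], dy = d[1] - e[1], dz = d[2] - e[2];
  ld al = ax * ax + ay * ay + az * az;
  ld bl = bx * bx + by * by + bz * bz;
  ld cl = cx * cx + cy * cy + cz * cz;
  ld dl = dx * dx + dy * dy + dz * dz;
  // det of 4x4 [[ax,ay,az,al],...] ; expand along the last column
  ld m1 = det3(bx, by, bz, cx, cy, cz, dx, dy, dz);
  ld m2 = det3(ax, ay, az, cx, cy, cz, dx, dy, dz);
  ld m3 = det3(ax, ay, az, bx, by, bz, dx, dy, dz);
  ld m4 = det3(ax, ay, az, bx, by, bz, cx, cy, cz);
  if (mag) {
    ld g1 = det3_mag(bx, by, bz, cx, cy, cz, dx, dy, dz);
    ld g2 = det3_mag(ax, ay, az, cx, cy, cz, dx, dy, dz);
    ld g3 = det3_mag(ax, ay, az, bx, by, bz, dx, dy, dz);
    ld g4 = det3_mag(ax, ay, az, bx, by, bz, cx, cy, cz);
    *mag = al * g1 + bl * g2 + cl * g3 + dl * g4;
  }
  return -(al * m1 - bl * m2 + cl * m3 - dl * m4);
}

// ---------------------------------------------------------------------------
// Incremental 3D Delaunay (Bowyer-Watson, infinite vertex)
// ---------------------------------------------------------------------------

struct Tet {
  int v[4];     // v[3] == -1 marks an infinite tet; (v0,v1,v2) hull face
  bool alive;
};

struct DelaunayResult {
  std::vector<std::array<int, 4>> tets; // finite tets, positively oriented
  bool degenerate = false;
};

static DelaunayResult delaunay3(const std::vector<std::array<double, 3>>& pts) {
  DelaunayResult res;
  const int n = (int)pts.size();
  double L = 1.0;
  for (auto& q : pts)
    for (int c = 0; c < 3; ++c) L = std::max(L, std::fabs(q[c]));
  const ld rel = 1e-14; // relative degeneracy threshold on predicate terms

  // initial affinely independent quadruple
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  for (int i = 1; i < n && i1 < 0; ++i) {
    ld d = 0;
    for (int c = 0; c < 3; ++c)
      d += ((ld)pts[i][c] - pts[i0][c]) * ((ld)pts[i][c] - pts[i0][c]);
    if (d > (ld)1e-20 * L * L) i1 = i;
  }
  for (int i = 1; i < n && i2 < 0; ++i) {
    if (i == i1) continue;
    ld ux = pts[i1][0] - pts[i0][0], uy = pts[i1][1] - pts[i0][1],
       uz = pts[i1][2] - pts[i0][2];
    ld vx = pts[i][0] - pts[i0][0], vy = pts[i][1] - pts[i0][1],
       vz = pts[i][2] - pts[i0][2];
    ld cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
    if (cx * cx + cy * cy + cz * cz > (ld)1e-20 * L * L * L * L) i2 = i;
  }
  for (int i = 1; i < n && i3 < 0; ++i) {
    if (i == i1 || i == i2) continue;
    ld mag = 0;
    ld o = orient3d_m(pts[i0].data(), pts[i1].data(), pts[i2].data(),
                      pts[i].data(), &mag);
    if (std::fabs((double)o) > (double)(rel * mag)) i3 = i;
  }
  if (i1 < 0 || i2 < 0 || i3 < 0) { res.degenerate = true; return res; }
  if (orient3d(pts[i0].data(), pts[i1].data(), pts[i2].data(),
               pts[i3].data()) < 0)
    std::swap(i1, i2);

  std::array<double, 3> c0 = { 0, 0, 0 };
  for (int c = 0; c < 3; ++c)
    c0[c] = (pts[i0][c] + pts[i1][c] + pts[i2][c] + pts[i3][c]) / 4.0;

  std::vector<Tet> T;
  auto add_finite = [&](int a, int b, int c, int d) {
    if (orient3d(pts[a].data(), pts[b].data(), pts[c].data(),
                 pts[d].data()) < 0)
      std::swap(a, b);
    T.push_back({ { a, b, c, d }, true });
  };
  auto add_infinite = [&](int a, int b, int c) {
    // orient hull face (a,b,c) outward: interior point on the negative side
    if (orient3d(pts[a].data(), pts[b].data(), pts[c].data(), c0.data()) > 0)
      std::swap(a, b);
    T.push_back({ { a, b, c, -1 }, true });
  };
  add_finite(i0, i1, i2, i3);
  add_infinite(i0, i1, i2);
  add_infinite(i0, i1, i3);
  add_infinite(i0, i2, i3);
  add_infinite(i1, i2, i3);

  bool degen = false;
  auto conflicts = [&](const Tet& t, int pi) -> bool {
    const double* p = pts[pi].data();
    if (t.v[3] >= 0) {
      ld mag = 0;
      ld s = insphere_m(pts[t.v[0]].data(), pts[t.v[1]].data(),
                        pts[t.v[2]].data(), pts[t.v[3]].data(), p, &mag);
      if (std::fabs((double)s) < (double)(rel * mag)) degen = true;
      return s > 0;
    }
    ld mag = 0;
    ld o = orient3d_m(pts[t.v[0]].data(), pts[t.v[1]].data(),
                      pts[t.v[2]].data(), p, &mag);
    if (std::fabs((double)o) < (double)(rel * mag)) degen = true;
    return o > 0;
  };

  std::vector<int> conf;
  for (int pi = 0; pi < n; ++pi) {
    if (pi == i0 || pi == i1 || pi == i2 || pi == i3) continue;
    conf.clear();
    for (size_t t = 0; t < T.size(); ++t)
      if (T[t].alive && conflicts(T[t], pi)) conf.push_back((int)t);
    if (conf.empty()) { res.degenerate = true; return res; }
    // face census over the conflict region
    std::map<std::array<int, 3>, int> faces;
    for (int t : conf) {
      for (int drop = 0; drop < 4; ++drop) {
        std::array<int, 3> f;
        int k = 0;
        for (int i = 0; i < 4; ++i)
          if (i != drop) f[k++] = T[t].v[i];
        std::sort(f.begin(), f.end());
        faces[f]++;
      }
      T[t].alive = false;
    }
    for (auto& fc : faces) {
      if (fc.second != 1) continue;
      const std::array<int, 3>& f = fc.first; // sorted; f[0] may be -1
      if (f[0] == -1) {
        // infinite boundary face (a, b, inf) -> infinite tet (a, b, p, inf)
        add_infinite(f[1], f[2], pi);
      } else {
        ld mag = 0;
        ld o = orient3d_m(pts[f[0]].data(), pts[f[1]].data(), pts[f[2]].data(),
                          pts[pi].data(), &mag);
        if (std::fabs((double)o) < (double)(rel * mag)) degen = true;
        add_finite(f[0], f[1], f[2], pi);
      }
    }
  }
  if (degen) { res.degenerate = true; return res; }
  for (auto& t : T)
    if (t.alive && t.v[3] >= 0)
      res.tets.push_back({ t.v[0], t.v[1], t.v[2], t.v[3] });
  return res;
}

// [[Rcpp::export]]
List cpp_delaunay(NumericMatrix X) {
  const int n = X.nrow();
  std::vector<std::array<double, 3>> pts(n);
  for (int i = 0; i < n; ++i) pts[i] = { X(i, 0), X(i, 1), X(i, 2) };
  DelaunayResult r = delaunay3(pts);
  IntegerMatrix tm(r.tets.size(), 4);
  for (size_t i = 0; i < r.tets.size(); ++i)
    for (int j = 0; j < 4; ++j) tm(i, j) = r.tets[i][j] + 1; // 1-based
  return List::create(_["tets"] = tm, _["degenerate"] = r.degenerate);
}

// ---------------------------------------------------------------------------
// Alpha filtration (squared circumradius + Gabriel propagation)
// ---------------------------------------------------------------------------

// squared circumradius and circumcenter of a k-simplex (k = 1, 2, 3) in R^3,
// i.e. the smallest sphere through all vertices within their affine hull
static void circumsphere(const std::vector<std::array<double, 3>>& pts,
                         const std::array<int, 4>& v, int d,
                         std::array<double, 3>& center, double& r2) {
  const double* a = pts[v[0]].data();
  if (d == 0) { center = pts[v[0]]; r2 = 0.0; return; }
  if (d == 1) {
    const double* b = pts[v[1]].data();
    double r = 0;
    for (int c = 0; c < 3; ++c) {
      center[c] = 0.5 * (a[c] + b[c]);
      r += (a[c] - b[c]) * (a[c] - b[c]);
    }
    r2 = r / 4.0;
  } else if (d == 2) {
    const double* b = pts[v[1]].data();
    const double* c = pts[v[2]].data();
    ld ux = b[0] - a[0], uy = b[1] - a[1], uz = b[2] - a[2];
    ld vx = c[0] - a[0], vy = c[1] - a[1], vz = c[2] - a[2];
    ld uu = ux * ux + uy * uy + uz * uz;
    ld vv = vx * vx + vy * vy + vz * vz;
    ld uv = ux * vx + uy * vy + uz * vz;
    ld det = uu * vv - uv * uv;
    if (det == 0) { r2 = R_PosInf; center = pts[v[0]]; return; }
    ld s = (uu / 2 * vv - vv / 2 * uv) / det;
    ld t = (uu * vv / 2 - uv * uu / 2) / det;
    ld px = s * ux + t * vx, py = s * uy + t * vy, pz = s * uz + t * vz;
    center = { (double)(a[0] + px), (double)(a[1] + py), (double)(a[2] + pz) };
    r2 = (double)(px * px + py * py + pz * pz);
  } else {
    const double* b = pts[v[1]].data();
    const double* c = pts[v[2]].data();
    const double* e = pts[v[3]].data();
    // rows 2(b-a), 2(c-a), 2(e-a); rhs |b|^2-|a|^2 etc. (shifted to a)
    ld m[3][3], rhs[3];
    const double* q[3] = { b, c, e };
    for (int r = 0; r < 3; ++r) {
      ld s = 0;
      for (int cc = 0; cc < 3; ++cc) {
        m[r][cc] = 2.0L * (q[r][cc] - a[cc]);
        s += ((ld)q[r][cc] - a[cc]) * ((ld)q[r][cc] - a[cc]);
      }
      rhs[r] = s;
    }
    ld det = det3(m[0][0], m[0][1], m[0][2], m[1][0], m[1][1], m[1][2],
                  m[2][0], m[2][1], m[2][2]);
    if (det == 0) { r2 = R_PosInf; center = pts[v[0]]; return; }
    ld x = det3(rhs[0], m[0][1], m[0][2], rhs[1], m[1][1], m[1][2],
                rhs[2], m[2][1], m[2][2]) / det;
    ld y = det3(m[0][0], rhs[0], m[0][2], m[1][0], rhs[1], m[1][2],
                m[2][0], rhs[2], m[2][2]) / det;
    ld z = det3(m[0][0], m[0][1], rhs[0], m[1][0], m[1][1], rhs[1],
                m[2][0], m[2][1], rhs[2]) / det;
    center = { (double)(a[0] + x), (double)(a[1] + y), (double)(a[2] + z) };
    r2 = (double)(x * x + y * y + z * z);
  }
}

static inline double dist2(const std::array<double, 3>& a, const double* b) {
  double s = 0;
  for (int c = 0; c < 3; ++c) s += (a[c] - b[c]) * (a[c] - b[c]);
  return s;
}

// Alpha persistence pairs on the SQUARED radius scale.
// Handles n <= 3 directly; n >= 4 via the Delaunay triangulation.
// [[Rcpp::export]]
List cpp_alpha_pairs(NumericMatrix X, int max_hom_dim) {
  const int n = X.nrow();
  if (n < 1) stop("empty point cloud");
  std::vector<std::array<double, 3>> pts(n);
  for (int i = 0; i < n; ++i) pts[i] = { X(i, 0), X(i, 1), X(i, 2) };

  Filtration F;
  F.n_vertices = n;

  std::map<std::array<int, 4>, int> idx; // simplex -> position in F
  auto add_unique = [&](std::array<int, 4> v, int d) -> int {
    std::sort(v.begin(), v.begin() + d + 1);
    for (int i = d + 1; i < 4; ++i) v[i] = -1;
    auto it = idx.find(v);
    if (it != idx.end()) return it->second;
    int pos = (int)F.size();
    F.verts.push_back(v);
    F.value.push_back(NA_REAL);
    F.dim.push_back(d);
    idx[v] = pos;
    return pos;
  };

  bool degenerate = false;

  if (n >= 4) {
    DelaunayResult dres = delaunay3(pts);
    if (dres.degenerate)
      return List::create(_["pairs"] = R_NilValue, _["degenerate"] = true);
    for (auto& t : dres.tets) {
      add_unique({ t[0], t[1], t[2], t[3] }, 3);
      for (int drop = 0; drop < 4; ++drop) {
        std::array<int, 4> f = { -1, -1, -1, -1 };
        int k = 0;
        for (int i = 0; i < 4; ++i)
          if (i != drop) f[k++] = t[i];
        add_unique(f, 2);
        // edges
      }
      for (int i = 0; i < 4; ++i)
        for (int j = i + 1; j < 4; ++j)
          add_unique({ t[i], t[j], -1, -1 }, 1);
    }
  } else if (n == 3) {
    // collinear -> path graph along the line; otherwise single triangle
    ld o2x, o2y, o2z;
    {
      ld ux = pts[1][0] - pts[0][0], uy = pts[1][1] - pts[0][1],
         uz = pts[1][2] - pts[0][2];
      ld vx = pts[2][0] - pts[0][0], vy = pts[2][1] - pts[0][1],
         vz = pts[2][2] - pts[0][2];
      o2x = uy * vz - uz * vy; o2y = uz * vx - ux * vz; o2z = ux * vy - uy * vx;
    }
    double L = 1.0;
    for (auto& q : pts)
      for (int c = 0; c < 3; ++c) L = std::max(L, std::fabs(q[c]));
    bool collinear =
        (double)(o2x * o2x + o2y * o2y + o2z * o2z) < 1e-20 * L * L * L * L;
    if (collinear) {
      // order along the dominant direction
      std::array<double, 3> dir = { pts[1][0] - pts[0][0],
                                    pts[1][1] - pts[0][1],
                                    pts[1][2] - pts[0][2] };
      std::vector<int> o = { 0, 1, 2 };
      std::sort(o.begin(), o.end(), [&](int a, int b) {
        double pa = 0, pb = 0;
        for (int c = 0; c < 3; ++c) {
          pa += pts[a][c] * dir[c];
          pb += pts[b][c] * dir[c];
        }
        return pa < pb;
      });
      add_unique({ o[0], o[1], -1, -1 }, 1);
      add_unique({ o[1], o[2], -1, -1 }, 1);
    } else {
      add_unique({ 0, 1, 2, -1 }, 2);
      add_unique({ 0, 1, -1, -1 }, 1);
      add_unique({ 0, 2, -1, -1 }, 1);
      add_unique({ 1, 2, -1, -1 }, 1);
    }
  } else if (n == 2) {
    add_unique({ 0, 1, -1, -1 }, 1);
  }
  for (int i = 0; i < n; ++i) add_unique({ i, -1, -1, -1 }, 0);

  // assign filtration values, high dimension to low (Gabriel propagation)
  const size_t m = F.size();
  std::vector<std::array<double, 3>> centers(m);
  std::vector<double> own_r2(m, NA_REAL);
  auto ensure_sphere = [&](int s) {
    if (!ISNA(own_r2[s])) return;
    double r2;
    circumsphere(pts, F.verts[s], F.dim[s], centers[s], r2);
    own_r2[s] = r2;
  };
  for (int d = 3; d >= 1; --d) {
    // pass A: own values for unset simplices of dim d, Gabriel assignment
    for (size_t s = 0; s < m; ++s) {
      if (F.dim[s] != d) continue;
      if (ISNA(F.value[s])) {
        ensure_sphere((int)s);
        F.value[s] = own_r2[s];
      }
      for (int drop = 0; drop <= d; ++drop) {
        std::array<int, 4> fv = { -1, -1, -1, -1 };
        int k = 0, opp = -1;
        for (int i = 0; i <= d; ++i) {
          if (i != drop) fv[k++] = F.verts[s][i];
          else opp = F.verts[s][i];
        }
        auto it = idx.find(fv);
        if (it == idx.end()) stop("internal error: missing facet");
        int t = it->second;
        if (!ISNA(F.value[t])) {
          if (F.value[s] < F.value[t]) F.value[t] = F.value[s];
        } else if (F.dim[t] > 0) {
          // vertices keep value 0; Gabriel applies to dims >= 1 only
          ensure_sphere(t);
          if (dist2(centers[t], pts[opp].data()) < own_r2[t])
            F.value[t] = F.value[s]; // opposite vertex inside: not Gabriel
        }
      }
    }
    // pass B: enforce monotonicity against every coface of this dimension
    for (size_t s = 0; s < m; ++s) {
      if (F.dim[s] != d) continue;
      for (int drop = 0; drop <= d; ++drop) {
        std::array<int, 4> fv = { -1, -1, -1, -1 };
        int k = 0;
        for (int i = 0; i <= d; ++i)
          if (i != drop) fv[k++] = F.verts[s][i];
        auto it = idx.find(fv);
        if (it == idx.end()) stop("internal error: missing facet");
        int t = it->second;
        if (!ISNA(F.value[t]) && F.value[t] > F.value[s])
          F.value[t] = F.value[s];
      }
    }
  }
  for (size_t s = 0; s < m; ++s)
    if (F.dim[s] == 0) F.value[s] = 0.0;

  NumericMatrix pairs = reduce_filtration(F, max_hom_dim);
  return List::create(_["pairs"] = pairs, _["degenerate"] = degenerate);
}
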