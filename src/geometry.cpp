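// Low-level 3D routines: separable Gaussian filtering, ball-structuring-element
// morphology, marching-tetrahedra iso-surfacing and an incremental 3D convex
// hull. These back the ROI morphometry and lesion-detection front ends in R.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // reflect-101-free simple mirror: ... 2 1 0 | 0 1 2 ... | n-1 n-1 ...
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - 1 - i;
  if (i < 0) i = 0;
  if (i >= n) i = n - 1;
  return i;
}

// [[Rcpp::export]]
NumericVector cv_gauss3d(NumericVector field, IntegerVector dim, NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(field.begin(), field.end()), b(a.size());
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.5 * s));
    std::vector<double> k(2 * r + 1);
    double ksum = 0.0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); ksum += k[i + r]; }
    for (double& v : k) v /= ksum;
    const int n = (ax == 0) ? nx : (ax == 1) ? ny : nz;
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) {
        int xx = x, yy = y, zz = z;
        if (ax == 0) xx = reflect_idx(x + i, n);
        else if (ax == 1) yy = reflect_idx(y + i, n);
        else zz = reflect_idx(z + i, n);
        acc += k[i + r] * a[(size_t)xx + nx * ((size_t)yy + (size_t)ny * zz)];
      }
      b[(size_t)x + nx * ((size_t)y + (size_t)ny * z)] = acc;
    }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
LogicalVector cv_ball_dilate(LogicalVector mask, IntegerVector dim, double radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int r = (int)std::floor(radius);
  std::vector<std::array<int, 3>> off;
  for (int dz = -r; dz <= r; ++dz) for (int dy = -r; dy <= r; ++dy) for (int dx = -r; dx <= r; ++dx)
    if ((double)dx * dx + dy * dy + dz * dz <= radius * radius) off.push_back({dx, dy, dz});
  LogicalVector out(mask.size(), false);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    if (!mask[(size_t)x + nx * ((size_t)y + (size_t)ny * z)]) continue;
    for (auto& o : off) {
      int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      out[(size_t)xx + nx * ((size_t)yy + (size_t)ny * zz)] = true;
    }
  }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
LogicalVector cv_ball_erode(LogicalVector mask, IntegerVector dim, double radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int r = (int)std::floor(radius);
  std::vector<std::array<int, 3>> off;
  for (int dz = -r; dz <= r; ++dz) for (int dy = -r; dy <= r; ++dy) for (int dx = -r; dx <= r; ++dx)
    if ((double)dx * dx + dy * dy + dz * dz <= radius * radius) off.push_back({dx, dy, dz});
  LogicalVector out(mask.size(), false);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    bool keep = true;
    for (auto& o : off) {
      int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) { keep = false; break; }
      if (!mask[(size_t)xx + nx * ((size_t)yy + (size_t)ny * zz)]) { keep = false; break; }
    }
    if (keep) out[(size_t)x + nx * ((size_t)y + (size_t)ny * z)] = true;
  }
  out.attr("dim") = dim;
  return out;
}

// ---- marching tetrahedra -------------------------------------------------
// Scalar field sampled at voxel centres, implicitly padded with zeros, so the
// level surface of any in-grid object is closed. Each cell is split into the
// six Kuhn tetrahedra sharing the main diagonal, which tile consistently
// across neighbouring cells.

struct MTAcc {
  std::vector<double> verts; // x,y,z triplets
  double area = 0.0;
};

static inline void mt_tri(MTAcc& acc, const double* p0, const double* p1, const double* p2) {
  double u[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  double v[3] = {p2[0] - p0[0], p2[1] - p0[1], p2[2] - p0[2]};
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  acc.area += 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
  for (const double* p : {p0, p1, p2}) { acc.verts.push_back(p[0]); acc.verts.push_back(p[1]); acc.verts.push_back(p[2]); }
}

// [[Rcpp::export]]
List cv_surface(NumericVector field, IntegerVector dim, NumericVector spacing, double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  auto val = [&](int x, int y, int z) -> double {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0.0;
    return field[(size_t)x + nx * ((size_t)y + (size_t)ny * z)];
  };
  static const int corner_off[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  static const int tets[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}};
  MTAcc acc;
  double cpos[8][3], cval[8];
  for (int z = -1; z < nz; ++z) for (int y = -1; y < ny; ++y) for (int x = -1; x < nx; ++x) {
    bool any_in = false, any_out = false;
    for (int c = 0; c < 8; ++c) {
      int cx = x + corner_off[c][0], cy = y + corner_off[c][1], cz = z + corner_off[c][2];
      cval[c] = val(cx, cy, cz);
      cpos[c][0] = cx * sx; cpos[c][1] = cy * sy; cpos[c][2] = cz * sz;
      (cval[c] > level ? any_in : any_out) = true;
    }
    if (!any_in || !any_out) continue;
    for (int t = 0; t < 6; ++t) {
      const int* tv = tets[t];
      int inside[4], nin = 0, outside[4], nout = 0;
      for (int j = 0; j < 4; ++j) (cval[tv[j]] > level ? inside[nin++] : outside[nout++]) = tv[j];
      if (nin == 0 || nin == 4) continue;
      auto interp = [&](int a, int b, double* out) {
        double t0 = (level - cval[a]) / (cval[b] - cval[a]);
        for (int d = 0; d < 3; ++d) out[d] = cpos[a][d] + t0 * (cpos[b][d] - cpos[a][d]);
      };
      double p[4][3];
      if (nin == 1) {
        for (int j = 0; j < 3; ++j) interp(inside[0], outside[j], p[j]);
        mt_tri(acc, p[0], p[1], p[2]);
      } else if (nin == 3) {
        for (int j = 0; j < 3; ++j) interp(outside[0], inside[j], p[j]);
        mt_tri(acc, p[0], p[1], p[2]);
      } else { // 2 in, 2 out: quad on edges (i0,o0),(i0,o1),(i1,o1),(i1,o0)
        interp(inside[0], outside[0], p[0]);
        interp(inside[0], outside[1], p[1]);
        interp(inside[1], outside[1], p[2]);
        interp(inside[1], outside[0], p[3]);
        mt_tri(acc, p[0], p[1], p[2]);
        mt_tri(acc, p[0], p[2], p[3]);
      }
    }
  }
  // deduplicate vertices on a fine grid hash (triangles repeat shared corners)
  std::unordered_map<std::uint64_t, int> seen;
  std::vector<double> uv;
  const double q = 1e-6 * (sx + sy + sz);
  for (size_t i = 0; i < acc.verts.size(); i += 3) {
    std::int64_t ix = (std::int64_t)std::llround(acc.verts[i] / q);
    std::int64_t iy = (std::int64_t)std::llround(acc.verts[i + 1] / q);
    std::int64_t iz = (std::int64_t)std::llround(acc.verts[i + 2] / q);
    std::uint64_t h = (std::uint64_t)ix * 73856093ULL ^ (std::uint64_t)iy * 19349663ULL ^ (std::uint64_t)iz * 83492791ULL;
    if (seen.emplace(h, 1).second) {
      uv.push_back(acc.verts[i]); uv.push_back(acc.verts[i + 1]); uv.push_back(acc.verts[i + 2]);
    }
  }
  NumericMatrix V(uv.size() / 3, 3);
  for (size_t i = 0; i < uv.size() / 3; ++i) for (int d = 0; d < 3; ++d) V(i, d) = uv[3 * i + d];
  return List::create(_["area"] = acc.area, _["vertices"] = V);
}

// ---- incremental 3D convex hull -----------------------------------------

struct HFace { int a, b, c; double n[3], d; bool alive; };

static inline void face_plane(const std::vector<double>& P, HFace& f, const double* inner) {
  const double *A = &P[3 * f.a], *B = &P[3 * f.b], *C = &P[3 * f.c];
  double u[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
  double v[3] = {C[0] - A[0], C[1] - A[1], C[2] - A[2]};
  f.n[0] = u[1] * v[2] - u[2] * v[1];
  f.n[1] = u[2] * v[0] - u[0] * v[2];
  f.n[2] = u[0] * v[1] - u[1] * v[0];
  f.d = f.n[0] * A[0] + f.n[1] * A[1] + f.n[2] * A[2];
  double side = f.n[0] * inner[0] + f.n[1] * inner[1] + f.n[2] * inner[2] - f.d;
  if (side > 0) { // flip so normal points away from interior
    std::swap(f.b, f.c);
    for (int d = 0; d < 3; ++d) f.n[d] = -f.n[d];
    f.d = -f.d;
  }
}

// [[Rcpp::export]]
List cv_convhull(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  std::vector<double> P(3 * (size_t)n);
  for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) P[3 * (size_t)i + d] = pts(i, d);
  // bounding-box scale for tolerances
  double lo[3] = {P[0], P[1], P[2]}, hi[3] = {P[0], P[1], P[2]};
  for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) {
    lo[d] = std::min(lo[d], P[3 * (size_t)i + d]); hi[d] = std::max(hi[d], P[3 * (size_t)i + d]);
  }
  double scale = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-12});
  double eps = 1e-9 * scale * scale; // plane offsets scale with area-like normals
  // initial tetrahedron: extremes along x, farthest from line, farthest from plane
  int i0 = 0, i1 = 0;
  for (int i = 0; i < n; ++i) {
    if (P[3 * (size_t)i] < P[3 * (size_t)i0]) i0 = i;
    if (P[3 * (size_t)i] > P[3 * (size_t)i1]) i1 = i;
  }
  if (i0 == i1) i1 = (i0 + 1) % n;
  auto dist2_line = [&](int i) {
    double ab[3], ap[3];
    for (int d = 0; d < 3; ++d) { ab[d] = P[3 * (size_t)i1 + d] - P[3 * (size_t)i0 + d]; ap[d] = P[3 * (size_t)i + d] - P[3 * (size_t)i0 + d]; }
    double cx = ab[1] * ap[2] - ab[2] * ap[1], cy = ab[2] * ap[0] - ab[0] * ap[2], cz = ab[0] * ap[1] - ab[1] * ap[0];
    double ab2 = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];
    return ab2 > 0 ? (cx * cx + cy * cy + cz * cz) / ab2 : 0.0;
  };
  int i2 = -1; double best = -1;
  for (int i = 0; i < n; ++i) { double d2 = dist2_line(i); if (d2 > best) { best = d2; i2 = i; } }
  if (best <= 1e-18 * scale * scale) stop("degenerate point set (collinear)");
  double u[3], v[3], nrm[3];
  for (int d = 0; d < 3; ++d) { u[d] = P[3 * (size_t)i1 + d] - P[3 * (size_t)i0 + d]; v[d] = P[3 * (size_t)i2 + d] - P[3 * (size_t)i0 + d]; }
  nrm[0] = u[1] * v[2] - u[2] * v[1]; nrm[1] = u[2] * v[0] - u[0] * v[2]; nrm[2] = u[0] * v[1] - u[1] * v[0];
  int i3 = -1; best = -1;
  for (int i = 0; i < n; ++i) {
    double h = 0; for (int d = 0; d < 3; ++d) h += nrm[d] * (P[3 * (size_t)i + d] - P[3 * (size_t)i0 + d]);
    if (std::fabs(h) > best) { best = std::fabs(h); i3 = i; }
  }
  if (best <= eps) stop("degenerate point set (coplanar)");
  double inner[3];
  for (int d = 0; d < 3; ++d)
    inner[d] = (P[3 * (size_t)i0 + d] + P[3 * (size_t)i1 + d] + P[3 * (size_t)i2 + d] + P[3 * (size_t)i3 + d]) / 4.0;
  std::vector<HFace> F;
  auto add_face = [&](int a, int b, int c) {
    HFace f{a, b, c, {0, 0, 0}, 0, true};
    face_plane(P, f, inner);
    F.push_back(f);
  };
  add_face(i0, i1, i2); add_face(i0, i1, i3); add_face(i0, i2, i3); add_face(i1, i2, i3);
  // deterministic shuffled insertion order
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::uint64_t rng = 88172645463325252ULL;
  for (int i = n - 1; i > 0; --i) {
    rng ^= rng << 13; rng ^= rng >> 7; rng ^= rng << 17;
    int j = (int)(rng % (std::uint64_t)(i + 1));
    std::swap(order[i], order[j]);
  }
  std::vector<int> visible;
  for (int oi = 0; oi < n; ++oi) {
    int pi = order[oi];
    if (pi == i0 || pi == i1 || pi == i2 || pi == i3) continue;
    const double* p = &P[3 * (size_t)pi];
    visible.clear();
    for (size_t fi = 0; fi < F.size(); ++fi) {
      if (!F[fi].alive) continue;
      if (F[fi].n[0] * p[0] + F[fi].n[1] * p[1] + F[fi].n[2] * p[2] - F[fi].d > eps) visible.push_back((int)fi);
    }
    if (visible.empty()) continue;
    // horizon = undirected edges used by exactly one visible face
    std::unordered_map<std::uint64_t, std::pair<int, int>> edges;
    std::unordered_map<std::uint64_t, int> cnt;
    auto ekey = [](int a, int b) {
      if (a > b) std::swap(a, b);
      return ((std::uint64_t)a << 32) | (std::uint64_t)(std::uint32_t)b;
    };
    for (int fi : visible) {
      const HFace& f = F[fi];
      int ev[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (auto& e : ev) {
        std::uint64_t k = ekey(e[0], e[1]);
        cnt[k]++;
        edges[k] = {e[0], e[1]};
      }
    }
    for (int fi : visible) F[fi].alive = false;
    for (auto& kv : cnt) if (kv.second == 1) {
      auto e = edges[kv.first];
      add_face(e.first, e.second, pi);
    }
    if (F.size() > 4000000) stop("convex hull exploded; input pathological");
  }
  double area = 0.0, vol = 0.0;
  for (const HFace& f : F) {
    if (!f.alive) continue;
    const double *A = &P[3 * (size_t)f.a], *B = &P[3 * (size_t)f.b], *C = &P[3 * (size_t)f.c];
    double u2[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
    double v2[3] = {C[0] - A[0], C[1] - A[1], C[2] - A[2]};
    double cx = u2[1] * v2[2] - u2[2] * v2[1];
    double cy = u2[2] * v2[0] - u2[0] * v2[2];
    double cz = u2[0] * v2[1] - u2[1] * v2[0];
    area += 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
    // signed volume of tetra (inner, A, B, C); normals point away from inner
    double a0[3] = {A[0] - inner[0], A[1] - inner[1], A[2] - inner[2]};
    double b0[3] = {B[0] - inner[0], B[1] - inner[1], B[2] - inner[2]};
    double c0[3] = {C[0] - inner[0], C[1] - inner[1], C[2] - inner[2]};
    double det = a0[0] * (b0[1] * c0[2] - b0[2] * c0[1])
               - a0[1] * (b0[0] * c0[2] - b0[2] * c0[0])
               + a0[2] * (b0[0] * c0[1] - b0[1] * c0[0]);
    vol += std::fabs(det) / 6.0;
  }
  return List::create(_["area"] = area, _["volume"] = vol);
}
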