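#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Isosurface by marching tetrahedra: each grid cell is split into six
// tetrahedra sharing the main diagonal; surface vertices are placed on
// tetrahedron edges by linear interpolation and welded through a global
// edge map, which makes the mesh watertight away from the grid boundary.
// "Inside" means value >= level; triangles are oriented with outward
// normals (away from the inside corners).

struct MTBuilder {
  const double* val;
  int nx, ny, nz;
  double level;
  const double* spacing;
  const double* origin;
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> verts;   // flat xyz
  std::vector<int> tris;       // flat 0-based

  inline R_xlen_t gid(int i, int j, int k) const {
    return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
  }
  int edge_point(R_xlen_t a, R_xlen_t b) {
    if (a > b) std::swap(a, b);
    uint64_t key = ((uint64_t)a << 32) | (uint64_t)b;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double va = val[a], vb = val[b];
    double t = (level - va) / (vb - va);
    int ai = (int)(a % nx), aj = (int)((a / nx) % ny), ak = (int)(a / ((R_xlen_t)nx * ny));
    int bi = (int)(b % nx), bj = (int)((b / nx) % ny), bk = (int)(b / ((R_xlen_t)nx * ny));
    double x = origin[0] + (ai + t * (bi - ai)) * spacing[0];
    double y = origin[1] + (aj + t * (bj - aj)) * spacing[1];
    double z = origin[2] + (ak + t * (bk - ak)) * spacing[2];
    int id = (int)(verts.size() / 3);
    verts.push_back(x); verts.push_back(y); verts.push_back(z);
    edge_vertex[key] = id;
    return id;
  }
  void emit(int v0, int v1, int v2, const double* inside_pt) {
    // orient so the normal points away from an interior point
    double ax = verts[3 * v0], ay = verts[3 * v0 + 1], az = verts[3 * v0 + 2];
    double bx = verts[3 * v1], by = verts[3 * v1 + 1], bz = verts[3 * v1 + 2];
    double cx = verts[3 * v2], cy = verts[3 * v2 + 1], cz = verts[3 * v2 + 2];
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double wx = cx - ax, wy = cy - ay, wz = cz - az;
    double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz, nzv = ux * wy - uy * wx;
    double dx = ax - inside_pt[0], dy = ay - inside_pt[1], dz = az - inside_pt[2];
    if (nxv * dx + nyv * dy + nzv * dz < 0) std::swap(v1, v2);
    tris.push_back(v0); tris.push_back(v1); tris.push_back(v2);
  }
  void do_tet(R_xlen_t n0, R_xlen_t n1, R_xlen_t n2, R_xlen_t n3) {
    R_xlen_t nd[4] = { n0, n1, n2, n3 };
    bool in[4];
    int nin = 0;
    for (int m = 0; m < 4; ++m) { in[m] = val[nd[m]] >= level; nin += in[m]; }
    if (nin == 0 || nin == 4) return;
    int ins[4], outs[4], ni = 0, no = 0;
    for (int m = 0; m < 4; ++m) (in[m] ? ins[ni++] : outs[no++]) = m;
    // interior reference point: centroid of inside corners
    double ip[3] = { 0, 0, 0 };
    for (int m = 0; m < ni; ++m) {
      R_xlen_t a = nd[ins[m]];
      int ai = (int)(a % nx), aj = (int)((a / nx) % ny), ak = (int)(a / ((R_xlen_t)nx * ny));
      ip[0] += origin[0] + ai * spacing[0];
      ip[1] += origin[1] + aj * spacing[1];
      ip[2] += origin[2] + ak * spacing[2];
    }
    ip[0] /= ni; ip[1] /= ni; ip[2] /= ni;
    if (nin == 1) {
      int e0 = edge_point(nd[ins[0]], nd[outs[0]]);
      int e1 = edge_point(nd[ins[0]], nd[outs[1]]);
      int e2 = edge_point(nd[ins[0]], nd[outs[2]]);
      emit(e0, e1, e2, ip);
    } else if (nin == 3) {
      int e0 = edge_point(nd[ins[0]], nd[outs[0]]);
      int e1 = edge_point(nd[ins[1]], nd[outs[0]]);
      int e2 = edge_point(nd[ins[2]], nd[outs[0]]);
      emit(e0, e1, e2, ip);
    } else {
      int e00 = edge_point(nd[ins[0]], nd[outs[0]]);
      int e01 = edge_point(nd[ins[0]], nd[outs[1]]);
      int e10 = edge_point(nd[ins[1]], nd[outs[0]]);
      int e11 = edge_point(nd[ins[1]], nd[outs[1]]);
      emit(e00, e01, e11, ip);
      emit(e00, e11, e10, ip);
    }
  }
};

// [[Rcpp::export(name = ".cpp_marching_tetra")]]
List cpp_marching_tetra(NumericVector values, IntegerVector dims, double level,
                        NumericVector spacing, NumericVector origin) {
  MTBuilder B;
  B.val = values.begin();
  B.nx = dims[0]; B.ny = dims[1]; B.nz = dims[2];
  B.level = level;
  B.spacing = spacing.begin();
  B.origin = origin.begin();
  int nx = B.nx, ny = B.ny, nz = B.nz;
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        R_xlen_t c0 = B.gid(i, j, k),       c1 = B.gid(i + 1, j, k);
        R_xlen_t c2 = B.gid(i + 1, j + 1, k), c3 = B.gid(i, j + 1, k);
        R_xlen_t c4 = B.gid(i, j, k + 1),   c5 = B.gid(i + 1, j, k + 1);
        R_xlen_t c6 = B.gid(i + 1, j + 1, k + 1), c7 = B.gid(i, j + 1, k + 1);
        // six tetrahedra around the c0-c6 diagonal
        B.do_tet(c0, c1, c2, c6);
        B.do_tet(c0, c2, c3, c6);
        B.do_tet(c0, c3, c7, c6);
        B.do_tet(c0, c7, c4, c6);
        B.do_tet(c0, c4, c5, c6);
        B.do_tet(c0, c5, c1, c6);
      }
  int nv = (int)(B.verts.size() / 3), nt = (int)(B.tris.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nt, 3);
  for (int v = 0; v < nv; ++v)
    for (int c = 0; c < 3; ++c) V(v, c) = B.verts[3 * v + c];
  for (int f = 0; f < nt; ++f)
    for (int c = 0; c < 3; ++c) F(f, c) = B.tris[3 * f + c] + 1;  // 1-based for R
  return List::create(_["vertices"] = V, _["triangles"] = F);
}

// --- closest point on triangle (Ericson, Real-Time Collision Detection) ---
static inline void closest_pt_tri(const double* p, const double* a, const double* b,
                                  const double* c, double* out) {
  double ab[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
  double ac[3] = { c[0] - a[0], c[1] - a[1], c[2] - a[2] };
  double ap[3] = { p[0] - a[0], p[1] - a[1], p[2] - a[2] };
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) { out[0] = a[0]; out[1] = a[1]; out[2] = a[2]; return; }
  double bp[3] = { p[0] - b[0], p[1] - b[1], p[2] - b[2] };
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) { out[0] = b[0]; out[1] = b[1]; out[2] = b[2]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int m = 0; m < 3; ++m) out[m] = a[m] + v * ab[m];
    return;
  }
  double cp[3] = { p[0] - c[0], p[1] - c[1], p[2] - c[2] };
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) { out[0] = c[0]; out[1] = c[1]; out[2] = c[2]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int m = 0; m < 3; ++m) out[m] = a[m] + w * ac[m];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int m = 0; m < 3; ++m) out[m] = b[m] + w * (c[m] - b[m]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int m = 0; m < 3; ++m) out[m] = a[m] + ab[m] * v + ac[m] * w;
}

// Nearest point / distance / nearest-triangle index for each query point.
// Triangle centroids are binned into a uniform grid; the search expands
// outward in Chebyshev shells of cells until no closer triangle can exist
// (per-triangle circumradii bound the centroid-vs-surface discrepancy).
// [[Rcpp::export(name = ".cpp_mesh_nearest")]]
List cpp_mesh_nearest(NumericMatrix pts, NumericMatrix V, IntegerMatrix F) {
  int np = pts.nrow(), nt = F.nrow();
  std::vector<double> cx(nt), cy(nt), cz(nt), rad(nt);
  double rmax = 0.0;
  double lo[3] = { 1e300, 1e300, 1e300 }, hi[3] = { -1e300, -1e300, -1e300 };
  for (int f = 0; f < nt; ++f) {
    int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    double mx = (V(i0, 0) + V(i1, 0) + V(i2, 0)) / 3.0;
    double my = (V(i0, 1) + V(i1, 1) + V(i2, 1)) / 3.0;
    double mz = (V(i0, 2) + V(i1, 2) + V(i2, 2)) / 3.0;
    cx[f] = mx; cy[f] = my; cz[f] = mz;
    lo[0] = std::min(lo[0], mx); hi[0] = std::max(hi[0], mx);
    lo[1] = std::min(lo[1], my); hi[1] = std::max(hi[1], my);
    lo[2] = std::min(lo[2], mz); hi[2] = std::max(hi[2], mz);
    double r2 = 0;
    for (int c = 0; c < 3; ++c) {
      int iv = F(f, c) - 1;
      double dx = V(iv, 0) - mx, dy = V(iv, 1) - my, dz = V(iv, 2) - mz;
      r2 = std::max(r2, dx * dx + dy * dy + dz * dz);
    }
    rad[f] = std::sqrt(r2);
    rmax = std::max(rmax, rad[f]);
  }
  // grid resolution: aim for a few triangles per cell
  double ext = std::max({ hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9 });
  int ncell = std::max(1, std::min(64, (int)std::cbrt((double)nt / 4.0 + 1.0)));
  double h = std::max(ext / ncell, 1e-9);
  int gx = (int)((hi[0] - lo[0]) / h) + 1;
  int gy = (int)((hi[1] - lo[1]) / h) + 1;
  int gz = (int)((hi[2] - lo[2]) / h) + 1;
  std::vector<std::vector<int> > cells((size_t)gx * gy * gz);
  auto cellOf = [&](double x, double y, double z, int& ci, int& cj, int& ck) {
    ci = std::min(gx - 1, std::max(0, (int)((x - lo[0]) / h)));
    cj = std::min(gy - 1, std::max(0, (int)((y - lo[1]) / h)));
    ck = std::min(gz - 1, std::max(0, (int)((z - lo[2]) / h)));
  };
  for (int f = 0; f < nt; ++f) {
    int ci, cj, ck;
    cellOf(cx[f], cy[f], cz[f], ci, cj, ck);
    cells[(size_t)ci + (size_t)gx * (cj + (size_t)gy * ck)].push_back(f);
  }
  int maxShell = std::max({ gx, gy, gz });
  NumericVector dist(np);
  NumericMatrix closest(np, 3);
  IntegerVector which_tri(np);
  for (int q = 0; q < np; ++q) {
    double p[3] = { pts(q, 0), pts(q, 1), pts(q, 2) };
    int pi, pj, pk;
    cellOf(p[0], p[1], p[2], pi, pj, pk);
    double best = 1e300, bp[3] = { 0, 0, 0 };
    int bf = -1;
    auto scan_cell = [&](int ci, int cj, int ck) {
      if (ci < 0 || ci >= gx || cj < 0 || cj >= gy || ck < 0 || ck >= gz) return;
      for (int f : cells[(size_t)ci + (size_t)gx * (cj + (size_t)gy * ck)]) {
        double dx = p[0] - cx[f], dy = p[1] - cy[f], dz = p[2] - cz[f];
        double lower = std::sqrt(dx * dx + dy * dy + dz * dz) - rad[f];
        if (lower > best) continue;
        int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
        double a[3] = { V(i0, 0), V(i0, 1), V(i0, 2) };
        double b[3] = { V(i1, 0), V(i1, 1), V(i1, 2) };
        double cc[3] = { V(i2, 0), V(i2, 1), V(i2, 2) };
        double q3[3];
        closest_pt_tri(p, a, b, cc, q3);
        double ddx = p[0] - q3[0], ddy = p[1] - q3[1], ddz = p[2] - q3[2];
        double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
        if (d < best) { best = d; bp[0] = q3[0]; bp[1] = q3[1]; bp[2] = q3[2]; bf = f; }
      }
    };
    for (int s = 0; s <= maxShell; ++s) {
      // no triangle in shell s or beyond can beat the current best
      if (bf >= 0 && (double)(s - 1) * h - rmax > best) break;
      if (s == 0) {
        scan_cell(pi, pj, pk);
        continue;
      }
      for (int ck = pk - s; ck <= pk + s; ++ck)
        for (int cj = pj - s; cj <= pj + s; ++cj)
          for (int ci = pi - s; ci <= pi + s; ++ci)
            if (std::max({ std::abs(ci - pi), std::abs(cj - pj), std::abs(ck - pk) }) == s)
              scan_cell(ci, cj, ck);
    }
    dist[q] = best;
    closest(q, 0) = bp[0]; closest(q, 1) = bp[1]; closest(q, 2) = bp[2];
    which_tri[q] = bf + 1;
  }
  return List::create(_["distance"] = dist, _["closest"] = closest,
                      _["triangle"] = which_tri);
}

// Signed enclosed volume via the divergence theorem (positive for outward
// orientation).
// [[Rcpp::export(name = ".cpp_mesh_volume")]]
double cpp_mesh_volume(NumericMatrix V, IntegerMatrix F) {
  double vol = 0.0;
  for (int f = 0; f < F.nrow(); ++f) {
    int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    double ax = V(i0, 0), ay = V(i0, 1), az = V(i0, 2);
    double bx = V(i1, 0), by = V(i1, 1), bz = V(i1, 2);
    double cx = V(i2, 0), cy = V(i2, 1), cz = V(i2, 2);
    vol += (ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) + az * (bx * cy - by * cx)) / 6.0;
  }
  return vol;
}
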