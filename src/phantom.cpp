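#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Analytic tooth/ligament/bone scene used by the phantom generator.
// Units mm, world coordinates; the tooth axis is +z, apex down.
//
// Root solid: convex hull of an apex sphere and a cemento-enamel-junction
// (CEJ) sphere ("round cone"), capped by the CEJ plane z = z_cej, so the
// lateral radius at the CEJ equals r_cej and the root length equals the
// apex-to-CEJ extent. Exact signed distance, so offset shells (the
// periodontal ligament, the bone socket wall) have true metric thickness.

struct RoundCone {
  double ax, ay, az;   // apex sphere centre
  double bx, by, bz;   // CEJ sphere centre
  double ra, rb;       // radii (ra apex < rb CEJ)
};

static inline double sd_round_cone(const RoundCone& c, double px, double py, double pz) {
  double ux = c.bx - c.ax, uy = c.by - c.ay, uz = c.bz - c.az;
  double h = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= h; uy /= h; uz /= h;
  double wx = px - c.ax, wy = py - c.ay, wz = pz - c.az;
  double z = wx * ux + wy * uy + wz * uz;
  double qx = std::sqrt(std::max(0.0, wx * wx + wy * wy + wz * wz - z * z));
  // 2D signed distance to hull of discs (0,0,ra) and (0,h,rb)
  double b = (c.ra - c.rb) / h;
  double a = std::sqrt(std::max(0.0, 1.0 - b * b));
  double k = qx * (-b) + z * a;
  if (k < 0.0) return std::sqrt(qx * qx + z * z) - c.ra;
  if (k > a * h) {
    double dz = z - h;
    return std::sqrt(qx * qx + dz * dz) - c.rb;
  }
  return qx * a + z * b - c.ra;
}

struct Scene {
  std::vector<RoundCone> roots;
  double z_cej;
  double crown_cx, crown_cy, crown_cz, crown_rx, crown_ry, crown_rz;
  double pdl_thickness;
  double z_bone_lo, z_crest;
  double z_apex_bottom;          // lowest root point (for the dentine gradient)
  double g_enamel, g_dent_crown, g_dent_apex, g_pdl, g_bone, g_bg;
};

static inline double sd_root(const Scene& s, double px, double py, double pz) {
  double d = 1e30;
  for (const RoundCone& c : s.roots) d = std::min(d, sd_round_cone(c, px, py, pz));
  return std::max(d, pz - s.z_cej);   // cap at the CEJ plane
}

static inline bool in_crown(const Scene& s, double px, double py, double pz) {
  if (pz < s.z_cej) return false;
  double ex = (px - s.crown_cx) / s.crown_rx;
  double ey = (py - s.crown_cy) / s.crown_ry;
  double ez = (pz - s.crown_cz) / s.crown_rz;
  return ex * ex + ey * ey + ez * ez <= 1.0;
}

static inline double scene_grey(const Scene& s, double px, double py, double pz) {
  double dr = sd_root(s, px, py, pz);
  if (dr <= 0.0) {
    double t = (pz - s.z_apex_bottom) / (s.z_cej - s.z_apex_bottom);
    t = std::min(1.0, std::max(0.0, t));
    return s.g_dent_apex + t * (s.g_dent_crown - s.g_dent_apex);
  }
  if (in_crown(s, px, py, pz)) return s.g_enamel;
  bool in_slab = pz >= s.z_bone_lo && pz <= s.z_crest;
  if (in_slab && dr <= s.pdl_thickness) return s.g_pdl;
  if (in_slab) return s.g_bone;
  return s.g_bg;
}

static Scene build_scene(List par) {
  Scene s;
  s.z_cej = as<double>(par["z_cej"]);
  s.pdl_thickness = as<double>(par["pdl_thickness"]);
  s.z_bone_lo = as<double>(par["z_bone_lo"]);
  s.z_crest = as<double>(par["z_crest"]);
  s.crown_cx = as<double>(par["crown_cx"]);
  s.crown_cy = as<double>(par["crown_cy"]);
  s.crown_cz = as<double>(par["crown_cz"]);
  s.crown_rx = as<double>(par["crown_rx"]);
  s.crown_ry = as<double>(par["crown_ry"]);
  s.crown_rz = as<double>(par["crown_rz"]);
  s.g_enamel = as<double>(par["grey_enamel"]);
  s.g_dent_crown = as<double>(par["grey_dentine_crown"]);
  s.g_dent_apex = as<double>(par["grey_dentine_apex"]);
  s.g_pdl = as<double>(par["grey_pdl"]);
  s.g_bone = as<double>(par["grey_bone"]);
  s.g_bg = as<double>(par["grey_background"]);
  NumericMatrix rc = as<NumericMatrix>(par["root_cones"]);  // rows: ax ay az bx by bz ra rb
  s.z_apex_bottom = 1e30;
  for (int r = 0; r < rc.nrow(); ++r) {
    RoundCone c = { rc(r, 0), rc(r, 1), rc(r, 2), rc(r, 3), rc(r, 4), rc(r, 5), rc(r, 6), rc(r, 7) };
    s.roots.push_back(c);
    s.z_apex_bottom = std::min(s.z_apex_bottom, c.az - c.ra);
  }
  return s;
}

// Rasterize the scene: each voxel is the mean of supersample^3 sub-samples
// of the analytic grey (box-filter partial-volume model). Also returns
// voxel-centre truth memberships.
// [[Rcpp::export(name = ".cpp_phantom_raster")]]
List cpp_phantom_raster(List par, IntegerVector dims, NumericVector spacing,
                        NumericVector origin, int supersample) {
  Scene s = build_scene(par);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector grey(n);
  LogicalVector t_tooth(n), t_root(n), t_pdl(n), t_bone(n);
  int ss = supersample;
  std::vector<double> off(ss);
  for (int m = 0; m < ss; ++m) off[m] = ((m + 0.5) / ss - 0.5);
  R_xlen_t t = 0;
  for (int k = 0; k < nz; ++k) {
    double cz = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double cy = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i, ++t) {
        double cx = origin[0] + i * spacing[0];
        double acc = 0.0;
        for (int mk = 0; mk < ss; ++mk)
          for (int mj = 0; mj < ss; ++mj)
            for (int mi = 0; mi < ss; ++mi)
              acc += scene_grey(s, cx + off[mi] * spacing[0],
                                   cy + off[mj] * spacing[1],
                                   cz + off[mk] * spacing[2]);
        grey[t] = acc / (double)(ss * ss * ss);
        double dr = sd_root(s, cx, cy, cz);
        bool root = dr <= 0.0;
        bool crown = in_crown(s, cx, cy, cz);
        bool slab = cz >= s.z_bone_lo && cz <= s.z_crest;
        t_root[t] = root;
        t_tooth[t] = root || crown;
        t_pdl[t] = !root && !crown && slab && dr <= s.pdl_thickness;
        t_bone[t] = !root && !crown && slab && dr > s.pdl_thickness;
      }
    }
  }
  grey.attr("dim") = dims;
  t_tooth.attr("dim") = dims; t_root.attr("dim") = dims;
  t_pdl.attr("dim") = dims; t_bone.attr("dim") = dims;
  return List::create(_["grey"] = grey, _["tooth"] = t_tooth, _["root"] = t_root,
                      _["pdl"] = t_pdl, _["bone"] = t_bone);
}

// Signed distance of the capped root solid on a grid (negative inside);
// used for the sub-voxel ground-truth mesh.
// [[Rcpp::export(name = ".cpp_root_sdf_grid")]]
NumericVector cpp_root_sdf_grid(List par, IntegerVector dims, NumericVector spacing,
                                NumericVector origin) {
  Scene s = build_scene(par);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t t = 0;
  for (int k = 0; k < nz; ++k) {
    double cz = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double cy = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i, ++t)
        out[t] = sd_root(s, origin[0] + i * spacing[0], cy, cz);
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Point evaluation of the root signed distance (oracle hooks for tests).
// [[Rcpp::export(name = ".cpp_root_sdf_points")]]
NumericVector cpp_root_sdf_points(List par, NumericMatrix pts) {
  Scene s = build_scene(par);
  NumericVector out(pts.nrow());
  for (int r = 0; r < pts.nrow(); ++r)
    out[r] = sd_root(s, pts(r, 0), pts(r, 1), pts(r, 2));
  return out;
}
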