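// Deterministic z-buffer rasterizer for canopy scenes.
//
// Geometry contract: every scene primitive is green vegetation, so the
// label pass needs coverage only (any hit at a subsample is green; the
// background plane lies behind every primitive).  Occlusion (z-buffer)
// matters only for shading, which runs at pixel-center resolution.
// Both passes consume the same projected geometry, so image and mask
// are aligned by construction.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 v3(double x, double y, double z) { return Vec3{x, y, z}; }
inline Vec3 sub(const Vec3 &a, const Vec3 &b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline Vec3 add(const Vec3 &a, const Vec3 &b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline Vec3 mul(const Vec3 &a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
inline double dot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline Vec3 normalize(const Vec3 &a) {
  double n = std::sqrt(dot(a, a));
  return n > 0 ? mul(a, 1.0 / n) : a;
}

// Deterministic integer hash -> [0, 1).  Used for soil mottling; all
// randomness in a render is a pure function of (coords, seed).
inline double hash01(int32_t ix, int32_t iy, int32_t seed) {
  uint32_t h = static_cast<uint32_t>(ix) * 374761393u ^
               static_cast<uint32_t>(iy) * 668265263u ^
               static_cast<uint32_t>(seed) * 2246822519u;
  h ^= h >> 13;
  h *= 1274126177u;
  h ^= h >> 16;
  return (h & 0x00FFFFFFu) / 16777216.0;
}

// Bilinear value noise at integer lattice `scale` cells per meter.
inline double value_noise(double x, double y, double scale, int32_t seed) {
  double fx = x * scale, fy = y * scale;
  double x0 = std::floor(fx), y0 = std::floor(fy);
  double tx = fx - x0, ty = fy - y0;
  int32_t ix = static_cast<int32_t>(x0), iy = static_cast<int32_t>(y0);
  double v00 = hash01(ix, iy, seed), v10 = hash01(ix + 1, iy, seed);
  double v01 = hash01(ix, iy + 1, seed), v11 = hash01(ix + 1, iy + 1, seed);
  double a = v00 + (v10 - v00) * tx;
  double b = v01 + (v11 - v01) * tx;
  return a + (b - a) * ty;
}

struct Camera {
  Vec3 pos, fwd, right, up;
  double focal;
  int res;
};

// Screen-space vertex: pixel coords (u right, v down) + camera depth.
struct SVert {
  double u, v, z;
  bool ok;
};

inline SVert project_vertex(const Vec3 &w, const Camera &cam) {
  Vec3 d = sub(w, cam.pos);
  double z = dot(d, cam.fwd);
  SVert s;
  s.z = z;
  if (z < 1e-6) {
    s.ok = false;
    s.u = s.v = 0;
    return s;
  }
  s.ok = true;
  double half = cam.res / 2.0;
  s.u = half + cam.focal * dot(d, cam.right) / z;
  s.v = half - cam.focal * dot(d, cam.up) / z;
  return s;
}

inline double edge_fn(double ax, double ay, double bx, double by, double px, double py) {
  return (bx - ax) * (py - ay) - (by - ay) * (px - ax);
}

// CCW 2-D triangle with scanline span queries: for sample row y
// (centres at py + 0.5) returns the inclusive [x0, x1] column span of
// inside samples.  Spans beat bounding boxes for the long thin
// diagonal triangles leaf strips produce.
struct Tri2D {
  double ax, ay, bx, by, cx, cy;
  double area;
  bool valid;
  Tri2D(double ax_, double ay_, double bx_, double by_, double cx_, double cy_) {
    ax = ax_; ay = ay_; bx = bx_; by = by_; cx = cx_; cy = cy_;
    area = edge_fn(ax, ay, bx, by, cx, cy);
    valid = std::fabs(area) >= 1e-12;
    flipped = false;
    if (valid && area < 0) {
      std::swap(bx, cx);
      std::swap(by, cy);
      area = -area;
      flipped = true;
    }
  }
  bool flipped;
  inline bool row_span(double sy, int lo_clamp, int hi_clamp, int &x0, int &x1) const {
    double lo = lo_clamp, hi = hi_clamp;
    const double ex[3] = {ax, bx, cx};
    const double ey[3] = {ay, by, cy};
    for (int e = 0; e < 3; ++e) {
      double x1v = ex[e], y1v = ey[e];
      double x2v = ex[(e + 1) % 3], y2v = ey[(e + 1) % 3];
      // edge value at sample x: (x2-x1)(sy-y1) - (y2-y1)(x - x1) >= 0
      double D = -(y2v - y1v);
      double C = (x2v - x1v) * (sy - y1v) + (y2v - y1v) * x1v;
      if (D > 1e-30) {
        lo = std::max(lo, std::ceil(-C / D - 0.5));
      } else if (D < -1e-30) {
        hi = std::min(hi, std::floor(-C / D - 0.5));
      } else if (C < 0) {
        return false;
      }
    }
    if (lo > hi) return false;
    x0 = static_cast<int>(lo);
    x1 = static_cast<int>(hi);
    return true;
  }
  inline void bary(double sx, double sy, double &l0, double &l1, double &l2) const {
    l0 = edge_fn(bx, by, cx, cy, sx, sy) / area;
    l1 = edge_fn(cx, cy, ax, ay, sx, sy) / area;
    l2 = 1.0 - l0 - l1;
  }
  inline int ymin() const { return static_cast<int>(std::floor(std::min({ay, by, cy}) - 0.5)); }
  inline int ymax() const { return static_cast<int>(std::ceil(std::max({ay, by, cy}) + 0.5)); }
};

} // namespace

// [[Rcpp::export(rng = false)]]
List raster_scene_cpp(NumericMatrix tri, NumericMatrix tricol,
                      NumericVector cam_pos, NumericVector cam_fwd,
                      NumericVector cam_right, NumericVector cam_up,
                      double focal, int res,
                      int bg_type, NumericVector bg_params,
                      int sunny, NumericVector sun_dir, double diffuse_fraction,
                      int subsamples, int seed) {
  const int n = tri.nrow();
  Camera cam;
  cam.pos = v3(cam_pos[0], cam_pos[1], cam_pos[2]);
  cam.fwd = v3(cam_fwd[0], cam_fwd[1], cam_fwd[2]);
  cam.right = v3(cam_right[0], cam_right[1], cam_right[2]);
  cam.up = v3(cam_up[0], cam_up[1], cam_up[2]);
  cam.focal = focal;
  cam.res = res;

  const Vec3 sun = normalize(v3(sun_dir[0], sun_dir[1], sun_dir[2]));

  // Project all vertices once.
  std::vector<SVert> sv(static_cast<size_t>(n) * 3);
  std::vector<Vec3> wv(static_cast<size_t>(n) * 3);
  std::vector<Vec3> nrm(n);
  for (int t = 0; t < n; ++t) {
    Vec3 a = v3(tri(t, 0), tri(t, 1), tri(t, 2));
    Vec3 b = v3(tri(t, 3), tri(t, 4), tri(t, 5));
    Vec3 c = v3(tri(t, 6), tri(t, 7), tri(t, 8));
    wv[3 * t] = a;
    wv[3 * t + 1] = b;
    wv[3 * t + 2] = c;
    sv[3 * t] = project_vertex(a, cam);
    sv[3 * t + 1] = project_vertex(b, cam);
    sv[3 * t + 2] = project_vertex(c, cam);
    nrm[t] = normalize(cross(sub(b, a), sub(c, a)));
  }

  // ---- label pass: subsample coverage -------------------------------
  const int ss = subsamples;
  const int S = res * ss;
  std::vector<uint8_t> cover(static_cast<size_t>(S) * S, 0);
  for (int t = 0; t < n; ++t) {
    const SVert &a = sv[3 * t], &b = sv[3 * t + 1], &c = sv[3 * t + 2];
    if (!a.ok || !b.ok || !c.ok) continue;
    Tri2D tr(a.u * ss, a.v * ss, b.u * ss, b.v * ss, c.u * ss, c.v * ss);
    if (!tr.valid) continue;
    int y0 = std::max(0, tr.ymin());
    int y1 = std::min(S - 1, tr.ymax());
    for (int py = y0; py <= y1; ++py) {
      int x0, x1;
      if (!tr.row_span(py + 0.5, 0, S - 1, x0, x1)) continue;
      uint8_t *row = cover.data() + static_cast<size_t>(py) * S;
      std::fill(row + x0, row + x1 + 1, static_cast<uint8_t>(1));
    }
  }

  // Majority vote per pixel; ties -> background.
  LogicalMatrix mask(res, res);
  const int majority = ss * ss / 2 + 1;
  for (int py = 0; py < res; ++py) {
    for (int px = 0; px < res; ++px) {
      int cnt = 0;
      for (int sy = 0; sy < ss; ++sy) {
        const uint8_t *row = cover.data() + static_cast<size_t>(py * ss + sy) * S + px * ss;
        for (int sx = 0; sx < ss; ++sx) cnt += row[sx];
      }
      mask(py, px) = cnt >= majority;
    }
  }

  // ---- shading pass: pixel-center z-buffer --------------------------
  std::vector<double> zbuf(static_cast<size_t>(res) * res,
                           std::numeric_limits<double>::infinity());
  std::vector<int> idbuf(static_cast<size_t>(res) * res, -1);
  for (int t = 0; t < n; ++t) {
    const SVert &a = sv[3 * t], &b = sv[3 * t + 1], &c = sv[3 * t + 2];
    if (!a.ok || !b.ok || !c.ok) continue;
    Tri2D tr(a.u, a.v, b.u, b.v, c.u, c.v);
    if (!tr.valid) continue;
    double za = a.z, zb = b.z, zc = c.z;
    if (tr.flipped) std::swap(zb, zc);
    int y0 = std::max(0, tr.ymin());
    int y1 = std::min(res - 1, tr.ymax());
    for (int py = y0; py <= y1; ++py) {
      double sy = py + 0.5;
      int x0, x1;
      if (!tr.row_span(sy, 0, res - 1, x0, x1)) continue;
      for (int px = x0; px <= x1; ++px) {
        double l0, l1, l2;
        tr.bary(px + 0.5, sy, l0, l1, l2);
        double invz = l0 / za + l1 / zb + l2 / zc; // perspective-correct
        double z = 1.0 / invz;
        size_t idx = static_cast<size_t>(py) * res + px;
        if (z < zbuf[idx]) {
          zbuf[idx] = z;
          idbuf[idx] = t;
        }
      }
    }
  }

  // ---- shadow map (hard shadows, sunny only) ------------------------
  const bool use_shadow = sunny != 0 && n > 0;
  int SM = 1024;
  std::vector<float> smap;
  Vec3 s_r = v3(1, 0, 0), s_u = v3(0, 1, 0);
  double sm_x0 = 0, sm_y0 = 0, sm_sx = 1, sm_sy = 1;
  if (use_shadow) {
    // orthonormal frame perpendicular to the sun direction
    Vec3 anyv = std::fabs(sun.z) < 0.9 ? v3(0, 0, 1) : v3(1, 0, 0);
    s_r = normalize(cross(sun, anyv));
    s_u = cross(sun, s_r);
    double a0 = std::numeric_limits<double>::infinity(), a1 = -a0;
    double b0 = a0, b1 = -a0;
    for (size_t i = 0; i < wv.size(); ++i) {
      double aa = dot(wv[i], s_r), bb = dot(wv[i], s_u);
      a0 = std::min(a0, aa); a1 = std::max(a1, aa);
      b0 = std::min(b0, bb); b1 = std::max(b1, bb);
    }
    double pad = 0.05;
    sm_x0 = a0 - pad; sm_y0 = b0 - pad;
    sm_sx = SM / std::max(1e-6, a1 - a0 + 2 * pad);
    sm_sy = SM / std::max(1e-6, b1 - b0 + 2 * pad);
    smap.assign(static_cast<size_t>(SM) * SM, std::numeric_limits<float>::infinity());
    for (int t = 0; t < n; ++t) {
      Vec3 A = wv[3 * t], B = wv[3 * t + 1], C = wv[3 * t + 2];
      double ax = (dot(A, s_r) - sm_x0) * sm_sx, ay = (dot(A, s_u) - sm_y0) * sm_sy;
      double bx = (dot(B, s_r) - sm_x0) * sm_sx, by = (dot(B, s_u) - sm_y0) * sm_sy;
      double cx = (dot(C, s_r) - sm_x0) * sm_sx, cy = (dot(C, s_u) - sm_y0) * sm_sy;
      // depth toward the sun: larger = farther from the sun
      double da = -dot(A, sun), db = -dot(B, sun), dc = -dot(C, sun);
      Tri2D tr(ax, ay, bx, by, cx, cy);
      if (!tr.valid) continue;
      if (tr.flipped) std::swap(db, dc);
      int y0 = std::max(0, tr.ymin());
      int y1 = std::min(SM - 1, tr.ymax());
      for (int py = y0; py <= y1; ++py) {
        double sy2 = py + 0.5;
        int x0, x1;
        if (!tr.row_span(sy2, 0, SM - 1, x0, x1)) continue;
        for (int px = x0; px <= x1; ++px) {
          double l0, l1, l2;
          tr.bary(px + 0.5, sy2, l0, l1, l2);
          double d = l0 * da + l1 * db + l2 * dc;
          size_t idx = static_cast<size_t>(py) * SM + px;
          if (d < smap[idx]) smap[idx] = static_cast<float>(d);
        }
      }
    }
  }

  // Is the world point lit by the direct sun beam?
  const double shadow_bias = 0.015;
  auto lit_at = [&](const Vec3 &w) -> double {
    if (!use_shadow) return 1.0;
    double a = (dot(w, s_r) - sm_x0) * sm_sx, b = (dot(w, s_u) - sm_y0) * sm_sy;
    int ix = static_cast<int>(std::floor(a)), iy = static_cast<int>(std::floor(b));
    if (ix < 0 || iy < 0 || ix >= SM || iy >= SM) return 1.0;
    double d = -dot(w, sun);
    return d <= smap[static_cast<size_t>(iy) * SM + ix] + shadow_bias ? 1.0 : 0.0;
  };

  // ---- shade --------------------------------------------------------
  const double df = diffuse_fraction;
  const double exposure = 1.45;
  IntegerVector rgb(static_cast<R_xlen_t>(res) * res * 3);
  rgb.attr("dim") = IntegerVector::create(res, res, 3);
  const double half = res / 2.0;
  const double sky_r = 0.78, sky_g = 0.84, sky_b = 0.92;
  for (int py = 0; py < res; ++py) {
    for (int px = 0; px < res; ++px) {
      // ray through the pixel center
      Vec3 dir = add(cam.fwd,
                     add(mul(cam.right, (px + 0.5 - half) / focal),
                         mul(cam.up, -(py + 0.5 - half) / focal)));
      double dn = std::sqrt(dot(dir, dir));
      Vec3 u = mul(dir, 1.0 / dn);
      size_t idx = static_cast<size_t>(py) * res + px;
      int t = idbuf[idx];
      double r, g, b;
      if (t >= 0) {
        // leaf surface: two-sided Lambertian
        double zfwd = zbuf[idx];
        Vec3 w = add(cam.pos, mul(dir, zfwd / dot(dir, cam.fwd)));
        double nd = std::fabs(dot(nrm[t], sun));
        double lit = lit_at(add(w, mul(nrm[t].z >= 0 ? nrm[t] : mul(nrm[t], -1.0), 0.004)));
        double E = df + (1.0 - df) * nd * lit;
        r = tricol(t, 0) * E;
        g = tricol(t, 1) * E;
        b = tricol(t, 2) * E;
      } else if (u.z < -1e-5) {
        // background plane z = 0
        double tg = -cam.pos.z / u.z;
        Vec3 w = add(cam.pos, mul(u, tg));
        double lit = lit_at(w);
        double E = df + (1.0 - df) * std::max(0.0, sun.z) * lit;
        if (bg_type == 1) {
          // soil: mottled brown, two noise octaves
          double m = 0.65 * value_noise(w.x, w.y, bg_params[3], seed) +
                     0.35 * value_noise(w.x, w.y, bg_params[4], seed + 7);
          double shade = 0.55 + 0.9 * m;
          r = bg_params[0] * shade * E;
          g = bg_params[1] * shade * E;
          b = bg_params[2] * shade * E;
        } else {
          // water: flat light gray + sun glint (specular lobe)
          double gray = bg_params[0];
          r = g = b = gray * E;
          if (sunny) {
            Vec3 refl = v3(sun.x, sun.y, -sun.z); // sun reflected off z=0
            double h = std::max(0.0, dot(refl, u));
            double spec = bg_params[1] * std::pow(h, bg_params[2]) * lit;
            r += spec; g += spec; b += spec;
          }
        }
      } else {
        r = sky_r; g = sky_g; b = sky_b;
      }
      auto to8 = [&](double v) {
        int q = static_cast<int>(std::lround(std::min(1.0, std::max(0.0, v * exposure)) * 255.0));
        return q;
      };
      // R arrays are column-major: (row, col, channel)
      size_t ridx = static_cast<size_t>(py) + static_cast<size_t>(px) * res;
      rgb[ridx] = to8(r);
      rgb[ridx + static_cast<size_t>(res) * res] = to8(g);
      rgb[ridx + 2 * static_cast<size_t>(res) * res] = to8(b);
    }
  }

  return List::create(_["rgb"] = rgb, _["mask"] = mask);
}
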