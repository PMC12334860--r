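// Dose-kernel and ray-tracing hot paths.
//
// Geometry convention (shared with the R side): voxel indices are 0-based
// here, world position of voxel (i,j,k) center = origin + (i,j,k)*spacing,
// arrays are column-major (index = i + nx*(j + ny*k)). The grid occupies
// [origin - spacing/2, origin + (dims-1/2)*spacing] per axis.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct GridInfo {
  int n[3];
  double sp[3];
  double lo[3], hi[3];
};

static GridInfo grid_info(const IntegerVector& dims,
                          const NumericVector& spacing,
                          const NumericVector& origin) {
  GridInfo g;
  for (int a = 0; a < 3; ++a) {
    g.n[a]  = dims[a];
    g.sp[a] = spacing[a];
    g.lo[a] = origin[a] - 0.5 * spacing[a];
    g.hi[a] = origin[a] + (dims[a] - 0.5) * spacing[a];
  }
  return g;
}

// Exact voxel traversal (Amanatides & Woo interval walking) of the segment
// p0 -> p1 clipped to the grid. The visitor receives the linear voxel index
// and the segment parameter interval [t_in, t_out] in [0, 1].
template <class F>
static void traverse_segment(const GridInfo& g, const double* p0,
                             const double* p1, F&& visit) {
  double d[3];
  for (int a = 0; a < 3; ++a) d[a] = p1[a] - p0[a];

  double t0 = 0.0, t1 = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (std::abs(d[a]) < 1e-12) {
      if (p0[a] <= g.lo[a] || p0[a] >= g.hi[a]) return;
    } else {
      double ta = (g.lo[a] - p0[a]) / d[a];
      double tb = (g.hi[a] - p0[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  if (t0 >= t1) return;

  const double nudge = 1e-10 * (t1 - t0);
  int idx[3], step[3];
  double tMax[3], tDelta[3];
  for (int a = 0; a < 3; ++a) {
    double ps = p0[a] + (t0 + nudge) * d[a];
    int i = (int)std::floor((ps - g.lo[a]) / g.sp[a]);
    idx[a] = std::min(std::max(i, 0), g.n[a] - 1);
    if (d[a] > 1e-12) {
      step[a]   = 1;
      tMax[a]   = (g.lo[a] + (idx[a] + 1) * g.sp[a] - p0[a]) / d[a];
      tDelta[a] = g.sp[a] / d[a];
    } else if (d[a] < -1e-12) {
      step[a]   = -1;
      tMax[a]   = (g.lo[a] + idx[a] * g.sp[a] - p0[a]) / d[a];
      tDelta[a] = -g.sp[a] / d[a];
    } else {
      step[a]   = 0;
      tMax[a]   = R_PosInf;
      tDelta[a] = R_PosInf;
    }
  }

  double tcur = t0;
  while (tcur < t1 - 1e-12) {
    int a = (tMax[0] <= tMax[1] && tMax[0] <= tMax[2])
              ? 0 : (tMax[1] <= tMax[2] ? 1 : 2);
    double tnext = std::min(tMax[a], t1);
    if (tnext > tcur) {
      int v = idx[0] + g.n[0] * (idx[1] + g.n[1] * idx[2]);
      visit(v, tcur, tnext);
    }
    tcur = tnext;
    if (tnext >= t1 - 1e-12) break;
    idx[a] += step[a];
    if (idx[a] < 0 || idx[a] >= g.n[a]) break;
    tMax[a] += tDelta[a];
  }
}

static double seg_len(const double* p0, const double* p1) {
  double s = 0.0;
  for (int a = 0; a < 3; ++a) s += (p1[a] - p0[a]) * (p1[a] - p0[a]);
  return std::sqrt(s);
}

// Water-equivalent path length: sum of geometric intersection length times
// voxel density over every voxel crossed by the (grid-clipped) segment.
// [[Rcpp::export]]
double cpp_radiological_path(NumericVector values, IntegerVector dims,
                             NumericVector spacing, NumericVector origin,
                             NumericVector p0, NumericVector p1) {
  GridInfo g = grid_info(dims, spacing, origin);
  const double* v = values.begin();
  double a0[3] = {p0[0], p0[1], p0[2]};
  double a1[3] = {p1[0], p1[1], p1[2]};
  double L = seg_len(a0, a1);
  double acc = 0.0;
  traverse_segment(g, a0, a1, [&](int vi, double ti, double to) {
    acc += (to - ti) * L * v[vi];
  });
  return acc;
}

// Walks inward from the grid boundary along -outward toward `point`,
// locates the outermost BODY crossing (the beam entry) and accumulates the
// radiological path from there to `point`. Returns
// (depth, entry_x, entry_y, entry_z, r_entry_unused=0, found).
static void entry_trace_impl(const GridInfo& g, const double* dens,
                             const int* body, const double* point,
                             const double* outward, double* out) {
  double diag = 0.0;
  for (int a = 0; a < 3; ++a) diag += (g.hi[a] - g.lo[a]) * (g.hi[a] - g.lo[a]);
  diag = std::sqrt(diag) + 1.0;
  double pfar[3];
  for (int a = 0; a < 3; ++a) pfar[a] = point[a] + diag * outward[a];

  double L = seg_len(pfar, point);
  bool found = false;
  double t_entry = 0.0, acc = 0.0;
  traverse_segment(g, pfar, point, [&](int vi, double ti, double to) {
    if (!found && body[vi]) { found = true; t_entry = ti; }
    if (found) acc += (to - ti) * L * dens[vi];
  });
  out[0] = acc;
  for (int a = 0; a < 3; ++a)
    out[1 + a] = pfar[a] + t_entry * (point[a] - pfar[a]);
  out[4] = found ? 1.0 : 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_entry_trace(NumericVector values, IntegerVector body,
                              IntegerVector dims, NumericVector spacing,
                              NumericVector origin, NumericVector point,
                              NumericVector outward) {
  GridInfo g = grid_info(dims, spacing, origin);
  double p[3] = {point[0], point[1], point[2]};
  double o[3] = {outward[0], outward[1], outward[2]};
  double out[5];
  entry_trace_impl(g, values.begin(), body.begin(), p, o, out);
  return NumericVector(out, out + 5);
}

// Convergent hollow-cone beam kernel, per unit weight:
//   focal term: anisotropic Gaussian aligned with the beam axis, peak 1 at
//     the focus, truncated at `trunc` sigma;
//   cone term (upstream of the focus only, polar angle within
//     [inner_rad, outer_rad] of the axis): entrance_frac times the
//     geometric convergence factor r_entry/max(r, r_floor) times
//     exp(-mu * radiological depth from the body entry along the ray
//     through the voxel and the focus).
// Dose is exactly zero outside BODY.
// [[Rcpp::export]]
NumericVector cpp_beam_dose(NumericVector values, IntegerVector body,
                            IntegerVector dims, NumericVector spacing,
                            NumericVector origin, NumericVector target,
                            NumericVector direction, double sigma_lat,
                            double sigma_long, double trunc,
                            double inner_rad, double outer_rad,
                            double entrance_frac, double mu,
                            double r_floor) {
  GridInfo g = grid_info(dims, spacing, origin);
  const double* dens = values.begin();
  const int* bd = body.begin();
  const int nx = g.n[0], ny = g.n[1], nz = g.n[2];
  NumericVector dose(values.size());

  const double tgt[3] = {target[0], target[1], target[2]};
  const double ax[3]  = {direction[0], direction[1], direction[2]};
  const double max_long = trunc * sigma_long;
  const double max_lat2 = trunc * sigma_lat * trunc * sigma_lat;
  const double sl2 = 2.0 * sigma_long * sigma_long;
  const double st2 = 2.0 * sigma_lat * sigma_lat;
  const double cos_inner = std::cos(inner_rad);
  const double cos_outer = std::cos(outer_rad);

  double out[5];
  int v = 0;
  for (int k = 0; k < nz; ++k) {
    double z = g.lo[2] + (k + 0.5) * g.sp[2];
    for (int j = 0; j < ny; ++j) {
      double y = g.lo[1] + (j + 0.5) * g.sp[1];
      for (int i = 0; i < nx; ++i, ++v) {
        if (!bd[v]) continue;
        double x = g.lo[0] + (i + 0.5) * g.sp[0];
        double rel[3] = {x - tgt[0], y - tgt[1], z - tgt[2]};
        double lz = rel[0] * ax[0] + rel[1] * ax[1] + rel[2] * ax[2];
        double r2 = rel[0] * rel[0] + rel[1] * rel[1] + rel[2] * rel[2];
        double lat2 = std::max(r2 - lz * lz, 0.0);
        double d = 0.0;
        if (std::abs(lz) <= max_long && lat2 <= max_lat2)
          d += std::exp(-(lz * lz / sl2 + lat2 / st2));
        if (entrance_frac > 0.0 && lz < 0.0 && r2 > 1e-12) {
          double r = std::sqrt(r2);
          double ca = -lz / r;  // cos of polar angle from the upstream axis
          if (ca <= cos_inner && ca >= cos_outer) {
            double outward[3] = {rel[0] / r, rel[1] / r, rel[2] / r};
            double p[3] = {x, y, z};
            entry_trace_impl(g, dens, bd, p, outward, out);
            if (out[4] > 0.5) {
              double re[3] = {out[1] - tgt[0], out[2] - tgt[1], out[3] - tgt[2]};
              double r_entry = std::sqrt(re[0] * re[0] + re[1] * re[1] +
                                         re[2] * re[2]);
              double geom = r_entry / std::max(r, r_floor);
              d += entrance_frac * geom * std::exp(-mu * out[0]);
            }
          }
        }
        dose[v] = d;
      }
    }
  }
  return dose;
}

// Batched depth-to-point evaluation over many candidate directions: one
// grid copy per target point instead of one per direction. Returns a
// 2-column matrix (depth, found).
// [[Rcpp::export]]
NumericMatrix cpp_depth_batch(NumericVector values, IntegerVector body,
                              IntegerVector dims, NumericVector spacing,
                              NumericVector origin, NumericVector point,
                              NumericMatrix directions) {
  GridInfo g = grid_info(dims, spacing, origin);
  int n = directions.nrow();
  NumericMatrix res(n, 2);
  double p[3] = {point[0], point[1], point[2]};
  double out[5];
  for (int i = 0; i < n; ++i) {
    double o[3] = {-directions(i, 0), -directions(i, 1), -directions(i, 2)};
    entry_trace_impl(g, values.begin(), body.begin(), p, o, out);
    res(i, 0) = out[4] > 0.5 ? out[0] : NA_REAL;
    res(i, 1) = out[4];
  }
  return res;
}
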