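// Voxel kernels shared by core_io, phantom, dose_engine.
// Array layout everywhere: dim = (nz slices, ny rows, nx cols), R column-major,
// so linear index = iz + nz*(iy + ny*ix).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double idx3(const NumericVector &a, int nz, int ny,
                          int iz, int iy, int ix) {
  return a[iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix)];
}

// Even-odd point-in-polygon (PNPOLY) for voxel centers of one slice.
// pts: n x 2 (row_mm, col_mm); rowC/colC: voxel-center coordinates (mm).
// [[Rcpp::export]]
LogicalMatrix cpp_rasterize_slice(NumericMatrix pts, NumericVector rowC,
                                  NumericVector colC) {
  int n = pts.nrow(), nr = rowC.size(), nc = colC.size();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nr; ++j) {
    double y = rowC[j];
    for (int k = 0; k < nc; ++k) {
      double x = colC[k];
      bool inside = false;
      for (int i = 0, p = n - 1; i < n; p = i++) {
        double yi = pts(i, 0), xi = pts(i, 1);
        double yp = pts(p, 0), xp = pts(p, 1);
        if (((yi > y) != (yp > y)) &&
            (x < (xp - xi) * (y - yi) / (yp - yi) + xi))
          inside = !inside;
      }
      out(j, k) = inside;
    }
  }
  return out;
}

static inline double trilinear(const NumericVector &a, int nz, int ny, int nx,
                               double fz, double fy, double fx,
                               double fill, bool nearest) {
  if (nearest) {
    int iz = (int)std::lround(fz), iy = (int)std::lround(fy),
        ix = (int)std::lround(fx);
    if (iz < 0 || iy < 0 || ix < 0 || iz >= nz || iy >= ny || ix >= nx)
      return fill;
    return idx3(a, nz, ny, iz, iy, ix);
  }
  if (fz < 0 || fy < 0 || fx < 0 || fz > nz - 1 || fy > ny - 1 || fx > nx - 1)
    return fill;
  int z0 = (int)std::floor(fz), y0 = (int)std::floor(fy),
      x0 = (int)std::floor(fx);
  int z1 = std::min(z0 + 1, nz - 1), y1 = std::min(y0 + 1, ny - 1),
      x1 = std::min(x0 + 1, nx - 1);
  double wz = fz - z0, wy = fy - y0, wx = fx - x0;
  double c00 = idx3(a, nz, ny, z0, y0, x0) * (1 - wx) +
               idx3(a, nz, ny, z0, y0, x1) * wx;
  double c01 = idx3(a, nz, ny, z0, y1, x0) * (1 - wx) +
               idx3(a, nz, ny, z0, y1, x1) * wx;
  double c10 = idx3(a, nz, ny, z1, y0, x0) * (1 - wx) +
               idx3(a, nz, ny, z1, y0, x1) * wx;
  double c11 = idx3(a, nz, ny, z1, y1, x0) * (1 - wx) +
               idx3(a, nz, ny, z1, y1, x1) * wx;
  double c0 = c00 * (1 - wy) + c01 * wy;
  double c1 = c10 * (1 - wy) + c11 * wy;
  return c0 * (1 - wz) + c1 * wz;
}

// Resample src onto target geometry. srcDim/tgtDim: (nz, ny, nx).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector srcDim,
                           NumericVector srcSpacing, NumericVector srcOrigin,
                           IntegerVector tgtDim, NumericVector tgtSpacing,
                           NumericVector tgtOrigin, bool nearest, double fill) {
  int nz = srcDim[0], ny = srcDim[1], nx = srcDim[2];
  int tz = tgtDim[0], ty = tgtDim[1], tx = tgtDim[2];
  NumericVector out((R_xlen_t)tz * ty * tx);
  for (int ix = 0; ix < tx; ++ix) {
    double xmm = tgtOrigin[2] + ix * tgtSpacing[2];
    double fx = (xmm - srcOrigin[2]) / srcSpacing[2];
    for (int iy = 0; iy < ty; ++iy) {
      double ymm = tgtOrigin[1] + iy * tgtSpacing[1];
      double fy = (ymm - srcOrigin[1]) / srcSpacing[1];
      for (int iz = 0; iz < tz; ++iz) {
        double zmm = tgtOrigin[0] + iz * tgtSpacing[0];
        double fz = (zmm - srcOrigin[0]) / srcSpacing[0];
        out[iz + (R_xlen_t)tz * (iy + (R_xlen_t)ty * ix)] =
          trilinear(src, nz, ny, nx, fz, fy, fx, fill, nearest);
      }
    }
  }
  return out;
}

// Warp: sample src at (voxel position + displacement). Displacements in mm.
// nearest = true resamples without interpolation (label maps, masks).
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector src, IntegerVector dims,
                       NumericVector spacing, NumericVector dz,
                       NumericVector dy, NumericVector dx, double fill,
                       bool nearest = false) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector out((R_xlen_t)nz * ny * nx);
  R_xlen_t idx = 0;
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz, ++idx) {
        double fz = iz + dz[idx] / spacing[0];
        double fy = iy + dy[idx] / spacing[1];
        double fx = ix + dx[idx] / spacing[2];
        out[idx] = trilinear(src, nz, ny, nx, fz, fy, fx, fill, nearest);
      }
  return out;
}

static inline double bilinear2(const NumericVector &a, int nz, int ny, int nx,
                               int iz, double fy, double fx) {
  // in-plane bilinear on slice iz, clamped at borders
  if (fy < 0) fy = 0; if (fx < 0) fx = 0;
  if (fy > ny - 1) fy = ny - 1; if (fx > nx - 1) fx = nx - 1;
  int y0 = (int)std::floor(fy), x0 = (int)std::floor(fx);
  int y1 = std::min(y0 + 1, ny - 1), x1 = std::min(x0 + 1, nx - 1);
  double wy = fy - y0, wx = fx - x0;
  double c0 = idx3(a, nz, ny, iz, y0, x0) * (1 - wx) +
              idx3(a, nz, ny, iz, y0, x1) * wx;
  double c1 = idx3(a, nz, ny, iz, y1, x0) * (1 - wx) +
              idx3(a, nz, ny, iz, y1, x1) * wx;
  return c0 * (1 - wy) + c1 * wy;
}

// Multi-beam parallel-ray dose with exponential attenuation along the
// radiological path and precomputed fluence maps.
// fluence: list of (nu x nz) matrices; u axis given by u0, du (mm).
// angles in radians; beam direction in (y, x) = (-cos a, -sin a).
// [[Rcpp::export]]
NumericVector cpp_dose(NumericVector red, IntegerVector dims,
                       NumericVector spacing, NumericVector origin,
                       NumericVector isocenter, NumericVector angles,
                       NumericVector weights, List fluence, double u0,
                       double du, double muEff, double stepMm) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int nb = angles.size();
  NumericVector out((R_xlen_t)nz * ny * nx);
  double ymin = origin[1], ymax = origin[1] + (ny - 1) * spacing[1];
  double xmin = origin[2], xmax = origin[2] + (nx - 1) * spacing[2];
  std::vector<NumericMatrix> fl;
  for (int b = 0; b < nb; ++b) fl.push_back(as<NumericMatrix>(fluence[b]));
  for (int b = 0; b < nb; ++b) {
    double a = angles[b], w = weights[b];
    double dyv = -std::cos(a), dxv = -std::sin(a);     // propagation dir
    int nu = fl[b].nrow();
    R_xlen_t idx = 0;
    for (int ix = 0; ix < nx; ++ix) {
      double xmm = origin[2] + ix * spacing[2];
      for (int iy = 0; iy < ny; ++iy) {
        double ymm = origin[1] + iy * spacing[1];
        // lateral BEV coordinate (same for all slices of this column)
        double u = (xmm - isocenter[2]) * std::cos(a) -
                   (ymm - isocenter[1]) * std::sin(a);
        double fu = (u - u0) / du;
        double flin0 = 0, flin1 = 0; int u0i = -1;
        if (fu >= 0 && fu <= nu - 1) {
          u0i = (int)std::floor(fu);
          int u1i = std::min(u0i + 1, nu - 1);
          double wu = fu - u0i;
          // per-slice fluence interpolated later; cache column weights
          flin0 = 1 - wu; flin1 = wu; (void)u1i;
        }
        for (int iz = 0; iz < nz; ++iz, ++idx) {
          if (u0i < 0) continue;
          int u1i = std::min(u0i + 1, nu - 1);
          double f = fl[b](u0i, iz) * flin0 + fl[b](u1i, iz) * flin1;
          if (f <= 1e-8) continue;
          // radiological path length with per-slice RED
          double path = 0, py = ymm, px = xmm;
          while (true) {
            double qy = py - dyv * stepMm, qx = px - dxv * stepMm;
            double my = 0.5 * (py + qy), mx = 0.5 * (px + qx);
            if (my < ymin || my > ymax || mx < xmin || mx > xmax) break;
            double fy = (my - origin[1]) / spacing[1];
            double fx = (mx - origin[2]) / spacing[2];
            path += bilinear2(red, nz, ny, nx, iz, fy, fx) * stepMm;
            py = qy; px = qx;
          }
          out[idx] += w * f * std::exp(-muEff * path);
        }
      }
    }
  }
  return out;
}

struct GOffset { double dz, dy, dx, dist2; };

// 3D local gamma with trilinear interpolation of the evaluated dose.
// thresholdAbs: absolute reference-dose cut; voxels below get NA.
// [[Rcpp::export]]
NumericVector cpp_gamma(NumericVector ref, NumericVector ev,
                        IntegerVector dims, NumericVector spacing,
                        double doseTol, double dta, double thresholdAbs,
                        double searchRadius, double stepMm) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<GOffset> offs;
  int mz = (int)std::ceil(searchRadius / stepMm);
  for (int oz = -mz; oz <= mz; ++oz)
    for (int oy = -mz; oy <= mz; ++oy)
      for (int ox = -mz; ox <= mz; ++ox) {
        double dz = oz * stepMm, dy = oy * stepMm, dx = ox * stepMm;
        double d2 = dz * dz + dy * dy + dx * dx;
        if (d2 <= searchRadius * searchRadius + 1e-9)
          offs.push_back({dz, dy, dx, d2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const GOffset &a, const GOffset &b) { return a.dist2 < b.dist2; });
  NumericVector out((R_xlen_t)nz * ny * nx);
  double dta2 = dta * dta;
  R_xlen_t idx = 0;
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz, ++idx) {
        double dref = ref[idx];
        if (dref < thresholdAbs) { out[idx] = NA_REAL; continue; }
        double denom = doseTol * dref;
        double best = R_PosInf;
        for (size_t o = 0; o < offs.size(); ++o) {
          double geo2 = offs[o].dist2 / dta2;
          if (geo2 >= best) break;  // offsets sorted: no better candidate left
          double fz = iz + offs[o].dz / spacing[0];
          double fy = iy + offs[o].dy / spacing[1];
          double fx = ix + offs[o].dx / spacing[2];
          double de = trilinear(ev, nz, ny, nx, fz, fy, fx, NA_REAL, false);
          if (ISNAN(de)) continue;
          double dd = (de - dref) / denom;
          double g2 = dd * dd + geo2;
          if (g2 < best) best = g2;
        }
        out[idx] = std::sqrt(best);
      }
  return out;
}
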