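#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dense numeric kernels for nonrigid parallel-beam tomography.
//
// Conventions (shared with the R layer):
//  * volumes are column-major arrays (nx fastest), continuous coordinates are
//    0-based voxel indices, the world origin sits at the volume centre
//    ((n-1)/2 in each axis), voxel centres at integer coordinates;
//  * fields evaluate to zero outside their grid;
//  * displacement fields are stored as three stacked scalar grids
//    (dx, dy, dz), possibly on a coarser grid with spacing `dstep` (in
//    voxels of the working volume); displacement grid point j sits at world
//    coordinate dstep * (j - (m-1)/2);
//  * curved operators are warp-composed: the forward operator projects the
//    pull-back-warped volume along straight rays, the transpose warp-gathers
//    the straight backprojection through the inverse displacement.  With a
//    zero displacement both reduce bit-exactly to the straight operators.

struct Grid3 {
  const double* v;
  int nx, ny, nz;
};

// branch-based floor: much cheaper than std::floor on targets without a
// hardware round instruction, valid for the coordinate ranges used here
static inline int ifloor(double x) {
  const int i = (int)x;
  return i - (x < (double)i);
}

static inline double tri_fetch(const Grid3& g, double x, double y, double z) {
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  if (x <= -1.0 || y <= -1.0 || z <= -1.0 ||
      x >= (double)nx || y >= (double)ny || z >= (double)nz)
    return 0.0;
  const int ix = ifloor(x);
  const int iy = ifloor(y);
  const int iz = ifloor(z);
  const double fx = x - ix, fy = y - iy, fz = z - iz;
  if (ix >= 0 && iy >= 0 && iz >= 0 &&
      ix < nx - 1 && iy < ny - 1 && iz < nz - 1) {
    const size_t nxy = (size_t)nx * ny;
    const double* p = g.v + ix + (size_t)nx * iy + nxy * iz;
    const double c00 = p[0] * (1 - fx) + p[1] * fx;
    const double c10 = p[nx] * (1 - fx) + p[nx + 1] * fx;
    const double p0 = c00 * (1 - fy) + c10 * fy;
    if (fz == 0.0) return p0;
    const double c01 = p[nxy] * (1 - fx) + p[nxy + 1] * fx;
    const double c11 = p[nxy + nx] * (1 - fx) + p[nxy + nx + 1] * fx;
    const double p1 = c01 * (1 - fy) + c11 * fy;
    return p0 * (1 - fz) + p1 * fz;
  }
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    const int z0 = iz + dz;
    if (z0 < 0 || z0 >= nz) continue;
    const double wz = dz ? fz : 1 - fz;
    if (wz == 0.0) continue;
    for (int dy = 0; dy < 2; ++dy) {
      const int y0 = iy + dy;
      if (y0 < 0 || y0 >= ny) continue;
      const double wy = dy ? fy : 1 - fy;
      if (wy == 0.0) continue;
      for (int dx = 0; dx < 2; ++dx) {
        const int x0 = ix + dx;
        if (x0 < 0 || x0 >= nx) continue;
        const double wx = dx ? fx : 1 - fx;
        acc += wz * wy * wx * g.v[x0 + (size_t)nx * y0 + (size_t)nx * ny * z0];
      }
    }
  }
  return acc;
}

// trilinear fetch of a 3-component displacement with shared weights
static inline void disp_fetch(const double* d, int mx, int my, int mz,
                              double x, double y, double z, double out[3]) {
  out[0] = out[1] = out[2] = 0.0;
  if (x <= -1.0 || y <= -1.0 || z <= -1.0 ||
      x >= (double)mx || y >= (double)my || z >= (double)mz)
    return;
  const int ix = ifloor(x);
  const int iy = ifloor(y);
  const int iz = ifloor(z);
  const double fx = x - ix, fy = y - iy, fz = z - iz;
  const size_t mxy = (size_t)mx * my, n = mxy * mz;
  if (ix >= 0 && iy >= 0 && iz >= 0 &&
      ix < mx - 1 && iy < my - 1 && iz < mz - 1) {
    const size_t base = ix + (size_t)mx * iy + mxy * iz;
    for (int c = 0; c < 3; ++c) {
      const double* p = d + c * n + base;
      const double c00 = p[0] * (1 - fx) + p[1] * fx;
      const double c10 = p[mx] * (1 - fx) + p[mx + 1] * fx;
      const double p0 = c00 * (1 - fy) + c10 * fy;
      if (fz == 0.0) { out[c] = p0; continue; }
      const double c01 = p[mxy] * (1 - fx) + p[mxy + 1] * fx;
      const double c11 = p[mxy + mx] * (1 - fx) + p[mxy + mx + 1] * fx;
      out[c] = p0 * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz;
    }
    return;
  }
  for (int c = 0; c < 3; ++c) {
    Grid3 g{d + c * n, mx, my, mz};
    out[c] = tri_fetch(g, x, y, z);
  }
}

// Pull-back warp with gather: dst(x) (+)= src~(x + disp(x)).
// The displacement grid is sampled trilinearly; the (y, z) interpolation is
// hoisted out of the inner x loop (the disp grid x coordinate is linear in
// the voxel x index), which makes the warp cheap even for coarse disp grids.
static void warp_gather(const double* src, int nx, int ny, int nz,
                        const double* disp, int mx, int my, int mz,
                        double dstep, double* dst, bool add) {
  const Grid3 g{src, nx, ny, nz};
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  const double mcx = (mx - 1) / 2.0, mcy = (my - 1) / 2.0, mcz = (mz - 1) / 2.0;
  const size_t mxy = (size_t)mx * my, mn = mxy * mz;
  // (y,z)-interpolated displacement components along the disp-grid x axis,
  // padded with one zero sample on each side (zero outside the grid)
  std::vector<double> line(3 * (mx + 2));
  const double stepinv = 1.0 / dstep;
  size_t idx = 0;
  for (int iz = 0; iz < nz; ++iz) {
    const double gz = (iz - cz) * stepinv + mcz;
    const int kz = ifloor(gz);
    const double fz = gz - kz;
    for (int iy = 0; iy < ny; ++iy) {
      const double gy = (iy - cy) * stepinv + mcy;
      const int ky = ifloor(gy);
      const double fy = gy - ky;
      std::fill(line.begin(), line.end(), 0.0);
      const bool inplane = gy > -1.0 && gy < (double)my &&
                           gz > -1.0 && gz < (double)mz;
      if (inplane) {
        for (int dz = 0; dz < 2; ++dz) {
          const int z0 = kz + dz;
          if (z0 < 0 || z0 >= mz) continue;
          const double wz = dz ? fz : 1 - fz;
          if (wz == 0.0) continue;
          for (int dy = 0; dy < 2; ++dy) {
            const int y0 = ky + dy;
            if (y0 < 0 || y0 >= my) continue;
            const double w = wz * (dy ? fy : 1 - fy);
            if (w == 0.0) continue;
            const size_t base = (size_t)mx * y0 + mxy * z0;
            for (int c = 0; c < 3; ++c) {
              const double* p = disp + c * mn + base;
              double* l = line.data() + c * (mx + 2) + 1;
              for (int k = 0; k < mx; ++k) l[k] += w * p[k];
            }
          }
        }
      }
      const double zw = iz - cz, yw = iy - cy;
      const double gx0 = -cx * stepinv + mcx;
      for (int ix = 0; ix < nx; ++ix, ++idx) {
        const double gx = gx0 + ix * stepinv;
        double d0 = 0, d1 = 0, d2 = 0;
        if (gx > -1.0 && gx < (double)mx) {
          const int kx = ifloor(gx);
          const double fx = gx - kx;
          const int o = kx + 1;  // padded index
          d0 = line[o] * (1 - fx) + line[o + 1] * fx;
          d1 = line[mx + 2 + o] * (1 - fx) + line[mx + 2 + o + 1] * fx;
          d2 = line[2 * (mx + 2) + o] * (1 - fx) + line[2 * (mx + 2) + o + 1] * fx;
        }
        const double v = tri_fetch(g, (ix - cx) + d0 + cx, yw + d1 + cy,
                                   zw + d2 + cz);
        if (add) dst[idx] += v; else dst[idx] = v;
      }
    }
  }
}

// In-plane ray sampling pattern for one (angle, detector column): the same
// (x, y) bilinear footprint applies to every detector row, so it is built
// once per column and reused across all rows.
struct RayPattern {
  std::vector<int> base;                    // ix + nx*iy of interior samples
  std::vector<double> w00, w10, w01, w11;   // their corner weights
  std::vector<double> bx, by;               // border samples (continuous)
  double ds;                                // line-integral weight per sample
  void clear() {
    base.clear(); w00.clear(); w01.clear(); w10.clear(); w11.clear();
    bx.clear(); by.clear();
  }
};

// Joseph-style sampling: the ray parameter advances so that the dominant
// in-plane axis moves exactly `ds`, making the along-ray interpolation comb
// an exact partition of unity at every angle; the per-sample line-integral
// weight is ds / max(|cos a|, |sin a|).
static void build_pattern(double angle, double uw, int nx, int ny,
                          double ds, double Rc, RayPattern& pat) {
  pat.clear();
  const double ca = std::cos(angle), sa = std::sin(angle);
  const double adom = std::max(std::fabs(ca), std::fabs(sa));
  const double ds_r = ds / adom;
  pat.ds = ds_r;
  const double rem = Rc * Rc - uw * uw;
  if (rem <= 0.0) return;
  const double smax = std::sqrt(rem);
  const int ns = (int)(2.0 * smax / ds_r) + 1;
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double x0 = -sa * uw - smax * ca + cx;
  const double y0 =  ca * uw - smax * sa + cy;
  const double dx = ca * ds_r, dy = sa * ds_r;
  for (int k = 0; k < ns; ++k) {
    const double x = x0 + k * dx, y = y0 + k * dy;
    if (x <= -1.0 || y <= -1.0 || x >= (double)nx || y >= (double)ny) continue;
    const int ix = ifloor(x), iy = ifloor(y);
    if (ix >= 0 && iy >= 0 && ix < nx - 1 && iy < ny - 1) {
      const double fx = x - ix, fy = y - iy;
      pat.base.push_back(ix + nx * iy);
      pat.w00.push_back((1 - fx) * (1 - fy));
      pat.w10.push_back(fx * (1 - fy));
      pat.w01.push_back((1 - fx) * fy);
      pat.w11.push_back(fx * fy);
    } else {
      pat.bx.push_back(x);
      pat.by.push_back(y);
    }
  }
}

static inline double plane_gather(const double* pl, int nx, int ny,
                                  const RayPattern& pat) {
  double acc = 0.0;
  const size_t n = pat.base.size();
  const int* b = pat.base.data();
  const double *a00 = pat.w00.data(), *a10 = pat.w10.data(),
               *a01 = pat.w01.data(), *a11 = pat.w11.data();
  for (size_t k = 0; k < n; ++k) {
    const double* p = pl + b[k];
    acc += a00[k] * p[0] + a10[k] * p[1] + a01[k] * p[nx] + a11[k] * p[nx + 1];
  }
  // border samples: bounds-checked bilinear
  for (size_t k = 0; k < pat.bx.size(); ++k) {
    const double x = pat.bx[k], y = pat.by[k];
    const int ix = ifloor(x), iy = ifloor(y);
    const double fx = x - ix, fy = y - iy;
    for (int dyy = 0; dyy < 2; ++dyy) {
      const int y0 = iy + dyy;
      if (y0 < 0 || y0 >= ny) continue;
      const double wy = dyy ? fy : 1 - fy;
      if (wy == 0.0) continue;
      for (int dxx = 0; dxx < 2; ++dxx) {
        const int x0 = ix + dxx;
        if (x0 < 0 || x0 >= nx) continue;
        acc += wy * (dxx ? fx : 1 - fx) * pl[x0 + nx * y0];
      }
    }
  }
  return acc;
}

static inline void plane_scatter(double* pl, int nx, int ny,
                                 const RayPattern& pat, double w) {
  const size_t n = pat.base.size();
  const int* b = pat.base.data();
  const double *a00 = pat.w00.data(), *a10 = pat.w10.data(),
               *a01 = pat.w01.data(), *a11 = pat.w11.data();
  for (size_t k = 0; k < n; ++k) {
    double* p = pl + b[k];
    p[0] += w * a00[k];
    p[1] += w * a10[k];
    p[nx] += w * a01[k];
    p[nx + 1] += w * a11[k];
  }
  for (size_t k = 0; k < pat.bx.size(); ++k) {
    const double x = pat.bx[k], y = pat.by[k];
    const int ix = ifloor(x), iy = ifloor(y);
    const double fx = x - ix, fy = y - iy;
    for (int dyy = 0; dyy < 2; ++dyy) {
      const int y0 = iy + dyy;
      if (y0 < 0 || y0 >= ny) continue;
      const double wy = dyy ? fy : 1 - fy;
      if (wy == 0.0) continue;
      for (int dxx = 0; dxx < 2; ++dxx) {
        const int x0 = ix + dxx;
        if (x0 < 0 || x0 >= nx) continue;
        pl[x0 + nx * y0] += w * wy * (dxx ? fx : 1 - fx);
      }
    }
  }
}

// Forward projection.  vol: nx*ny*nz; output nu*nv*np.  disp_ (optional):
// per-projection forward displacement grids, mx*my*mz*3*np.
// [[Rcpp::export]]
NumericVector cpp_project(NumericVector vol, IntegerVector vdim,
                          NumericVector angles, int nu, int nv, double ds,
                          Nullable<NumericVector> disp_, IntegerVector mdim,
                          double dstep) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const int np = angles.size();
  const size_t nxy = (size_t)nx * ny, nvox = nxy * nz;
  const bool curved = disp_.isNotNull();
  NumericVector disp;
  const double* dp = nullptr;
  size_t dframe = 0;
  int mx = 0, my = 0, mz = 0;
  if (curved) {
    disp = disp_.get();
    mx = mdim[0]; my = mdim[1]; mz = mdim[2];
    dframe = (size_t)mx * my * mz * 3;
    dp = disp.begin();
  }
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  const double cu = (nu - 1) / 2.0, cv = (nv - 1) / 2.0;
  const double Rc = std::sqrt((cx + 1) * (cx + 1) + (cy + 1) * (cy + 1)) + 1;
  NumericVector out((size_t)nu * nv * np);
  std::vector<double> wbuf(curved ? nvox : 0);
  RayPattern pat;
  for (int j = 0; j < np; ++j) {
    const double* src = vol.begin();
    if (curved) {
      warp_gather(vol.begin(), nx, ny, nz, dp + dframe * j, mx, my, mz,
                  dstep, wbuf.data(), false);
      src = wbuf.data();
    }
    double* oj = out.begin() + (size_t)nu * nv * j;
    for (int iu = 0; iu < nu; ++iu) {
      build_pattern(angles[j], iu - cu, nx, ny, ds, Rc, pat);
      if (pat.base.empty() && pat.bx.empty()) continue;
      for (int iv = 0; iv < nv; ++iv) {
        const double z = (iv - cv) + cz;
        if (z <= -1.0 || z >= (double)nz) continue;
        const int iz = ifloor(z);
        const double fz = z - iz;
        double acc = 0.0;
        if (iz >= 0)
          acc += (1 - fz) * plane_gather(src + nxy * iz, nx, ny, pat);
        if (fz != 0.0 && iz + 1 < nz)
          acc += fz * plane_gather(src + nxy * (iz + 1), nx, ny, pat);
        oj[iu + (size_t)nu * iv] = acc * pat.ds;
      }
    }
  }
  return out;
}

// Transpose under the same sampling rule.  disp_ (optional): per-projection
// INVERSE displacement grids (the caller prepares Gamma^{-1}).
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector proj, int nu, int nv,
                              NumericVector angles, IntegerVector vdim,
                              double ds,
                              Nullable<NumericVector> disp_, IntegerVector mdim,
                              double dstep) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const int np = angles.size();
  const size_t nxy = (size_t)nx * ny, nvox = nxy * nz;
  const bool curved = disp_.isNotNull();
  NumericVector disp;
  const double* dp = nullptr;
  size_t dframe = 0;
  int mx = 0, my = 0, mz = 0;
  if (curved) {
    disp = disp_.get();
    mx = mdim[0]; my = mdim[1]; mz = mdim[2];
    dframe = (size_t)mx * my * mz * 3;
    dp = disp.begin();
  }
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  const double cu = (nu - 1) / 2.0, cv = (nv - 1) / 2.0;
  const double Rc = std::sqrt((cx + 1) * (cx + 1) + (cy + 1) * (cy + 1)) + 1;
  NumericVector out(nvox);
  std::vector<double> bbuf(nvox);
  RayPattern pat;
  for (int j = 0; j < np; ++j) {
    std::fill(bbuf.begin(), bbuf.end(), 0.0);
    const double* pj = proj.begin() + (size_t)nu * nv * j;
    for (int iu = 0; iu < nu; ++iu) {
      build_pattern(angles[j], iu - cu, nx, ny, ds, Rc, pat);
      if (pat.base.empty() && pat.bx.empty()) continue;
      for (int iv = 0; iv < nv; ++iv) {
        const double w = pj[iu + (size_t)nu * iv] * pat.ds;
        if (w == 0.0) continue;
        const double z = (iv - cv) + cz;
        if (z <= -1.0 || z >= (double)nz) continue;
        const int iz = ifloor(z);
        const double fz = z - iz;
        if (iz >= 0)
          plane_scatter(bbuf.data() + nxy * iz, nx, ny, pat, w * (1 - fz));
        if (fz != 0.0 && iz + 1 < nz)
          plane_scatter(bbuf.data() + nxy * (iz + 1), nx, ny, pat, w * fz);
      }
    }
    if (curved) {
      warp_gather(bbuf.data(), nx, ny, nz, dp + dframe * j, mx, my, mz,
                  dstep, out.begin(), true);
    } else {
      double* o = out.begin();
      const double* b = bbuf.data();
      for (size_t i = 0; i < nvox; ++i) o[i] += b[i];
    }
  }
  return out;
}

// Pull-back warp of a volume: out(x) = vol(x + disp(x)).
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector vol, IntegerVector vdim,
                       NumericVector disp, IntegerVector mdim, double dstep) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  NumericVector out((size_t)nx * ny * nz);
  warp_gather(vol.begin(), nx, ny, nz, disp.begin(),
              mdim[0], mdim[1], mdim[2], dstep, out.begin(), false);
  return out;
}

// Resample a displacement field (3 stacked grids, spacing dstep) onto the
// full-resolution grid vdim; component values are untouched.
// [[Rcpp::export]]
NumericVector cpp_upscale_disp(NumericVector disp, IntegerVector mdim,
                               double dstep, IntegerVector vdim) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const int mx = mdim[0], my = mdim[1], mz = mdim[2];
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  const double mcx = (mx - 1) / 2.0, mcy = (my - 1) / 2.0, mcz = (mz - 1) / 2.0;
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(nvox * 3);
  double* ov = out.begin();
  const double* dpv = disp.begin();
  size_t idx = 0;
  for (int iz = 0; iz < nz; ++iz) {
    const double zi = (iz - cz) / dstep + mcz;
    for (int iy = 0; iy < ny; ++iy) {
      const double yi = (iy - cy) / dstep + mcy;
      for (int ix = 0; ix < nx; ++ix, ++idx) {
        const double xi = (ix - cx) / dstep + mcx;
        double d[3];
        disp_fetch(dpv, mx, my, mz, xi, yi, zi, d);
        ov[idx] = d[0];
        ov[idx + nvox] = d[1];
        ov[idx + 2 * nvox] = d[2];
      }
    }
  }
  return out;
}

// clamp-to-edge displacement fetch: used by the fixed-point inversion so
// that rigid (constant) fields invert exactly up to the grid boundary
static inline void disp_fetch_clamped(const double* d, int mx, int my, int mz,
                                      double x, double y, double z,
                                      double out[3]) {
  if (x < 0) x = 0; else if (x > mx - 1) x = mx - 1;
  if (y < 0) y = 0; else if (y > my - 1) y = my - 1;
  if (z < 0) z = 0; else if (z > mz - 1) z = mz - 1;
  disp_fetch(d, mx, my, mz, x, y, z, out);
}

// Fixed-point inversion of a displacement field on its own grid:
// v_{k+1}(x) = -disp(x + v_k(x)), v_0 = -disp(x).  Returns the inverse
// field and the mean composition residual |v_k + disp(x + v_k)| after each
// iteration.
// [[Rcpp::export]]
List cpp_invert_grid(NumericVector disp, IntegerVector mdim, double dstep,
                     int n_iter) {
  const int mx = mdim[0], my = mdim[1], mz = mdim[2];
  const size_t n = (size_t)mx * my * mz;
  const double* dpv = disp.begin();
  NumericVector inv(n * 3);
  double* iv = inv.begin();
  for (size_t i = 0; i < 3 * n; ++i) iv[i] = -dpv[i];
  NumericVector res(n_iter);
  std::vector<double> buf(3 * n);
  for (int it = 0; it < n_iter; ++it) {
    double acc = 0.0;
    size_t idx = 0;
    for (int iz = 0; iz < mz; ++iz) {
      for (int iy = 0; iy < my; ++iy) {
        for (int ix = 0; ix < mx; ++ix, ++idx) {
          const double vx = iv[idx], vy = iv[idx + n], vz = iv[idx + 2 * n];
          double d[3];
          disp_fetch_clamped(dpv, mx, my, mz,
                             ix + vx / dstep, iy + vy / dstep,
                             iz + vz / dstep, d);
          buf[idx] = -d[0];
          buf[idx + n] = -d[1];
          buf[idx + 2 * n] = -d[2];
          const double ex = vx + d[0], ey = vy + d[1], ez = vz + d[2];
          acc += std::sqrt(ex * ex + ey * ey + ez * ez);
        }
      }
    }
    std::copy(buf.begin(), buf.end(), iv);
    res[it] = acc / (double)n;
  }
  return List::create(_["field"] = inv, _["residual"] = res);
}

// Displacement at arbitrary world points (N x 3 matrix).
// [[Rcpp::export]]
NumericMatrix cpp_disp_at_points(NumericVector disp, IntegerVector mdim,
                                 double dstep, NumericMatrix pts) {
  const int mx = mdim[0], my = mdim[1], mz = mdim[2];
  const double mcx = (mx - 1) / 2.0, mcy = (my - 1) / 2.0, mcz = (mz - 1) / 2.0;
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  const double* dpv = disp.begin();
  for (int i = 0; i < n; ++i) {
    double d[3];
    disp_fetch(dpv, mx, my, mz,
               pts(i, 0) / dstep + mcx,
               pts(i, 1) / dstep + mcy,
               pts(i, 2) / dstep + mcz, d);
    out(i, 0) = d[0]; out(i, 1) = d[1]; out(i, 2) = d[2];
  }
  return out;
}

// Fixed-point inverse displacements at arbitrary world points.
// [[Rcpp::export]]
List cpp_invert_points(NumericVector disp, IntegerVector mdim, double dstep,
                       NumericMatrix pts, int n_iter) {
  const int mx = mdim[0], my = mdim[1], mz = mdim[2];
  const double mcx = (mx - 1) / 2.0, mcy = (my - 1) / 2.0, mcz = (mz - 1) / 2.0;
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  NumericVector res(n_iter);
  const double* dpv = disp.begin();
  for (int i = 0; i < n; ++i) {
    double d[3];
    disp_fetch(dpv, mx, my, mz,
               pts(i, 0) / dstep + mcx, pts(i, 1) / dstep + mcy,
               pts(i, 2) / dstep + mcz, d);
    out(i, 0) = -d[0]; out(i, 1) = -d[1]; out(i, 2) = -d[2];
  }
  for (int it = 0; it < n_iter; ++it) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      double d[3];
      disp_fetch_clamped(dpv, mx, my, mz,
                         (pts(i, 0) + out(i, 0)) / dstep + mcx,
                         (pts(i, 1) + out(i, 1)) / dstep + mcy,
                         (pts(i, 2) + out(i, 2)) / dstep + mcz, d);
      const double ex = out(i, 0) + d[0], ey = out(i, 1) + d[1],
                   ez = out(i, 2) + d[2];
      acc += std::sqrt(ex * ex + ey * ey + ez * ez);
      out(i, 0) = -d[0]; out(i, 1) = -d[1]; out(i, 2) = -d[2];
    }
    res[it] = acc / (double)std::max(n, 1);
  }
  return List::create(_["disp"] = out, _["residual"] = res);
}

// Separable convolution of a 3-D grid with a 1-D kernel along all three
// axes (zero boundary).  Used for Gaussian smoothing.
// [[Rcpp::export]]
NumericVector cpp_conv3_sep(NumericVector vol, IntegerVector vdim,
                            NumericVector kernel) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const int kl = kernel.size(), half = kl / 2;
  const size_t n = (size_t)nx * ny * nz;
  NumericVector a(clone(vol));
  NumericVector b(n);
  const double* kp = kernel.begin();
  const int dims[3] = {nx, ny, nz};
  const size_t strides[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int axis = 0; axis < 3; ++axis) {
    const int len = dims[axis];
    const size_t st = strides[axis];
    double* src = a.begin();
    double* dst = b.begin();
    const int d1 = dims[(axis + 1) % 3], d2 = dims[(axis + 2) % 3];
    const size_t s1 = strides[(axis + 1) % 3], s2 = strides[(axis + 2) % 3];
    for (int i2 = 0; i2 < d2; ++i2) {
      for (int i1 = 0; i1 < d1; ++i1) {
        const size_t base = s1 * i1 + s2 * i2;
        for (int i = 0; i < len; ++i) {
          const int lo = std::max(0, i - half);
          const int hi = std::min(len - 1, i + half);
          double acc = 0.0;
          for (int t = lo; t <= hi; ++t)
            acc += kp[half + (i - t)] * src[base + st * t];
          dst[base + st * i] = acc;
        }
      }
    }
    std::swap(a, b);
  }
  return a;
}

// Bilinear image translation by (du, dv): out(u, v) = img(u - du, v - dv),
// zero-filled outside.
// [[Rcpp::export]]
NumericMatrix cpp_shift_image(NumericMatrix img, double du, double dv) {
  const int nu = img.nrow(), nv = img.ncol();
  NumericMatrix out(nu, nv);
  for (int j = 0; j < nv; ++j) {
    const double yv = j - dv;
    if (yv <= -1.0 || yv >= (double)nv) continue;
    const int jy = ifloor(yv);
    const double fy = yv - jy;
    for (int i = 0; i < nu; ++i) {
      const double xu = i - du;
      if (xu <= -1.0 || xu >= (double)nu) continue;
      const int jx = ifloor(xu);
      const double fx = xu - jx;
      double acc = 0.0;
      for (int dy = 0; dy < 2; ++dy) {
        const int y0 = jy + dy;
        if (y0 < 0 || y0 >= nv) continue;
        const double wy = dy ? fy : 1 - fy;
        if (wy == 0.0) continue;
        for (int dx = 0; dx < 2; ++dx) {
          const int x0 = jx + dx;
          if (x0 < 0 || x0 >= nu) continue;
          const double wx = dx ? fx : 1 - fx;
          acc += wy * wx * img(x0, y0);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}
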