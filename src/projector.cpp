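#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a 3-D grid at a physical point given in the
// volume frame. Grid values live at voxel centers origin + index * vox
// (0-based indices); the field is 0 outside the span of voxel centers.
static inline double trilinear(const double *v, const int *dim,
                               const double *vox, const double *org,
                               double x, double y, double z) {
  double fx = (x - org[0]) / vox[0];
  double fy = (y - org[1]) / vox[1];
  double fz = (z - org[2]) / vox[2];
  if (fx < 0.0 || fy < 0.0 || fz < 0.0 ||
      fx > dim[0] - 1.0 || fy > dim[1] - 1.0 || fz > dim[2] - 1.0)
    return 0.0;
  int ix = (int)fx, iy = (int)fy, iz = (int)fz;
  if (ix == dim[0] - 1) ix--;
  if (iy == dim[1] - 1) iy--;
  if (iz == dim[2] - 1) iz--;
  if (ix < 0) ix = 0;
  if (iy < 0) iy = 0;
  if (iz < 0) iz = 0;
  double tx = fx - ix, ty = fy - iy, tz = fz - iz;
  const R_xlen_t nx = dim[0], nxy = (R_xlen_t)dim[0] * dim[1];
  const double *p = v + ix + (R_xlen_t)iy * nx + (R_xlen_t)iz * nxy;
  double c00 = p[0] * (1 - tx) + p[1] * tx;
  double c10 = p[nx] * (1 - tx) + p[nx + 1] * tx;
  double c01 = p[nxy] * (1 - tx) + p[nxy + 1] * tx;
  double c11 = p[nxy + nx] * (1 - tx) + p[nxy + nx + 1] * tx;
  double c0 = c00 * (1 - ty) + c10 * ty;
  double c1 = c01 * (1 - ty) + c11 * ty;
  return c0 * (1 - tz) + c1 * tz;
}

// [[Rcpp::export(name = ".trilinearCpp")]]
NumericVector trilinear_cpp(NumericVector vol, IntegerVector dim,
                            NumericVector voxelSize, NumericVector origin,
                            NumericMatrix points) {
  int n = points.nrow();
  NumericVector out(n);
  int d[3] = {dim[0], dim[1], dim[2]};
  double vx[3] = {voxelSize[0], voxelSize[1], voxelSize[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  for (int i = 0; i < n; i++)
    out[i] = trilinear(REAL(vol), d, vx, org,
                       points(i, 0), points(i, 1), points(i, 2));
  return out;
}

// Cone-beam line integrals: for each detector pixel, march the source->pixel
// ray through the volume with a fixed step (midpoint rule, trilinear
// samples) and return the integral in mm. The rigid pose maps volume-frame
// coordinates into the geometry frame: x_geo = R x_vol + t.
// [[Rcpp::export(name = ".forwardProjectCpp")]]
NumericMatrix forward_project_cpp(NumericVector vol, IntegerVector dim,
                                  NumericVector voxelSize, NumericVector origin,
                                  NumericMatrix rot, NumericVector trans,
                                  NumericVector source, NumericVector detOrigin,
                                  NumericMatrix detAxes, double pixelPitch,
                                  IntegerVector detShape, double stepFactor) {
  const int npx = detShape[0], npy = detShape[1];
  NumericMatrix out(npx, npy);
  int d[3] = {dim[0], dim[1], dim[2]};
  double vx[3] = {voxelSize[0], voxelSize[1], voxelSize[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  double minvox = std::min(vx[0], std::min(vx[1], vx[2]));
  double step = stepFactor * minvox;

  // source in volume frame: s_v = R^T (s - t)
  double sv[3];
  for (int a = 0; a < 3; a++) {
    double acc = 0.0;
    for (int b = 0; b < 3; b++) acc += rot(b, a) * (source[b] - trans[b]);
    sv[a] = acc;
  }
  // bounding box of voxel-center span
  double lo[3], hi[3];
  for (int a = 0; a < 3; a++) {
    lo[a] = org[a];
    hi[a] = org[a] + (d[a] - 1.0) * vx[a];
  }
  const double *vptr = REAL(vol);
  for (int j = 0; j < npy; j++) {
    for (int i = 0; i < npx; i++) {
      double pg[3], pv[3];
      for (int a = 0; a < 3; a++)
        pg[a] = detOrigin[a] + i * pixelPitch * detAxes(a, 0) +
                j * pixelPitch * detAxes(a, 1);
      for (int a = 0; a < 3; a++) {
        double acc = 0.0;
        for (int b = 0; b < 3; b++) acc += rot(b, a) * (pg[b] - trans[b]);
        pv[a] = acc;
      }
      double dir[3], len = 0.0;
      for (int a = 0; a < 3; a++) {
        dir[a] = pv[a] - sv[a];
        len += dir[a] * dir[a];
      }
      len = std::sqrt(len);
      for (int a = 0; a < 3; a++) dir[a] /= len;
      // slab clipping against the bbox
      double tmin = 0.0, tmax = len;
      bool miss = false;
      for (int a = 0; a < 3; a++) {
        if (std::fabs(dir[a]) < 1e-12) {
          if (sv[a] < lo[a] || sv[a] > hi[a]) { miss = true; break; }
        } else {
          double t1 = (lo[a] - sv[a]) / dir[a];
          double t2 = (hi[a] - sv[a]) / dir[a];
          if (t1 > t2) std::swap(t1, t2);
          if (t1 > tmin) tmin = t1;
          if (t2 < tmax) tmax = t2;
          if (tmin > tmax) { miss = true; break; }
        }
      }
      if (miss || tmax <= tmin) { out(i, j) = 0.0; continue; }
      int nsteps = (int)std::ceil((tmax - tmin) / step);
      if (nsteps < 1) nsteps = 1;
      double h = (tmax - tmin) / nsteps;
      double acc = 0.0;
      for (int k = 0; k < nsteps; k++) {
        double t = tmin + (k + 0.5) * h;
        acc += trilinear(vptr, d, vx, org, sv[0] + t * dir[0],
                         sv[1] + t * dir[1], sv[2] + t * dir[2]);
      }
      out(i, j) = acc * h;
    }
  }
  return out;
}
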