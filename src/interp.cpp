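#include <Rcpp.h>
#include <cmath>
#include "sampling.h"
using namespace Rcpp;

// Resample `vox` (geometry mov_*) onto an output lattice; each output voxel's
// world position w is mapped to R*w + t before sampling.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector vox, IntegerVector mdim,
                                  NumericVector mspacing, NumericVector morigin,
                                  IntegerVector odim, NumericVector ospacing,
                                  NumericVector oorigin, NumericMatrix R,
                                  NumericVector t, bool linear, double bg) {
  int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((size_t)ox * oy * oz);
  const double* v = vox.begin();
  double r00 = R(0, 0), r01 = R(0, 1), r02 = R(0, 2);
  double r10 = R(1, 0), r11 = R(1, 1), r12 = R(1, 2);
  double r20 = R(2, 0), r21 = R(2, 1), r22 = R(2, 2);
  size_t q = 0;
  for (int k = 0; k < oz; k++) {
    double wz = oorigin[2] + ospacing[2] * k;
    for (int j = 0; j < oy; j++) {
      double wy = oorigin[1] + ospacing[1] * j;
      for (int i = 0; i < ox; i++, q++) {
        double wx = oorigin[0] + ospacing[0] * i;
        double mx = r00 * wx + r01 * wy + r02 * wz + t[0];
        double my = r10 * wx + r11 * wy + r12 * wz + t[1];
        double mz = r20 * wx + r21 * wy + r22 * wz + t[2];
        double px = (mx - morigin[0]) / mspacing[0];
        double py = (my - morigin[1]) / mspacing[1];
        double pz = (mz - morigin[2]) / mspacing[2];
        out[q] = linear ? es_sample_lin(v, nx, ny, nz, px, py, pz, bg)
                        : es_sample_nn(v, nx, ny, nz, px, py, pz, bg);
      }
    }
  }
  out.attr("dim") = odim;
  return out;
}

// Pull-back warp: out(x) = vox(x + U(x)), U in mm on the same lattice.
// [[Rcpp::export]]
NumericVector warp_field_cpp(NumericVector vox, IntegerVector dim,
                             NumericVector spacing, NumericVector ux,
                             NumericVector uy, NumericVector uz, bool linear,
                             double bg) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz);
  const double* v = vox.begin();
  size_t q = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, q++) {
        double px = i + ux[q] / spacing[0];
        double py = j + uy[q] / spacing[1];
        double pz = k + uz[q] / spacing[2];
        out[q] = linear ? es_sample_lin(v, nx, ny, nz, px, py, pz, bg)
                        : es_sample_nn(v, nx, ny, nz, px, py, pz, bg);
      }
  out.attr("dim") = dim;
  return out;
}

// Straightened CPR sampling: slice s covers origin[s] + (i-c)*sp*u[s] +
// (j-c)*sp*v[s] for i,j in 0..(n_in-1), c = (n_in-1)/2.
// [[Rcpp::export]]
NumericVector straighten_cpp(NumericVector vox, IntegerVector dim,
                             NumericVector spacing, NumericVector origin,
                             NumericMatrix cl, NumericMatrix uax,
                             NumericMatrix vax, int n_in, double sp,
                             bool linear, double bg) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ns = cl.nrow();
  NumericVector out((size_t)n_in * n_in * ns);
  const double* v = vox.begin();
  double c = (n_in - 1) / 2.0;
  size_t q = 0;
  for (int s = 0; s < ns; s++) {
    double ox = cl(s, 0), oy = cl(s, 1), oz = cl(s, 2);
    double ux_ = uax(s, 0), uy_ = uax(s, 1), uz_ = uax(s, 2);
    double vx_ = vax(s, 0), vy_ = vax(s, 1), vz_ = vax(s, 2);
    for (int j = 0; j < n_in; j++) {
      double b = (j - c) * sp;
      for (int i = 0; i < n_in; i++, q++) {
        double a = (i - c) * sp;
        double wx = ox + a * ux_ + b * vx_;
        double wy = oy + a * uy_ + b * vy_;
        double wz = oz + a * uz_ + b * vz_;
        double px = (wx - origin[0]) / spacing[0];
        double py = (wy - origin[1]) / spacing[1];
        double pz = (wz - origin[2]) / spacing[2];
        out[q] = linear ? es_sample_lin(v, nx, ny, nz, px, py, pz, bg)
                        : es_sample_nn(v, nx, ny, nz, px, py, pz, bg);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(n_in, n_in, ns);
  return out;
}

// Mean squared intensity difference between fixed values at given world
// coordinates and the moving image sampled at R*w + t (trilinear). Samples
// mapping outside the moving volume are excluded (a background fill would
// bias the optimum whenever rigid motion clips anatomy at the field of
// view); if fewer than a quarter of the samples land inside, the transform
// is treated as invalid (huge metric).
// [[Rcpp::export]]
double msd_rigid_cpp(NumericVector fvals, NumericMatrix coords,
                     NumericVector vox, IntegerVector dim,
                     NumericVector spacing, NumericVector origin,
                     NumericMatrix R, NumericVector t, double bg) {
  int n = fvals.size();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = vox.begin();
  double r00 = R(0, 0), r01 = R(0, 1), r02 = R(0, 2);
  double r10 = R(1, 0), r11 = R(1, 1), r12 = R(1, 2);
  double r20 = R(2, 0), r21 = R(2, 1), r22 = R(2, 2);
  double acc = 0;
  int inside = 0;
  for (int q = 0; q < n; q++) {
    double wx = coords(q, 0), wy = coords(q, 1), wz = coords(q, 2);
    double mx = r00 * wx + r01 * wy + r02 * wz + t[0];
    double my = r10 * wx + r11 * wy + r12 * wz + t[1];
    double mz = r20 * wx + r21 * wy + r22 * wz + t[2];
    double px = (mx - origin[0]) / spacing[0];
    double py = (my - origin[1]) / spacing[1];
    double pz = (mz - origin[2]) / spacing[2];
    if (px < 0 || py < 0 || pz < 0 || px > nx - 1 || py > ny - 1 ||
        pz > nz - 1)
      continue;
    double s = es_sample_lin(v, nx, ny, nz, px, py, pz, bg);
    double d = fvals[q] - s;
    acc += d * d;
    inside++;
  }
  if (inside < n / 4) return 1e30;
  return acc / inside;
}
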