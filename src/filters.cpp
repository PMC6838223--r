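#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

#include "smoothing.h"

// [[Rcpp::export]]
NumericVector gaussian_smooth3_cpp(NumericVector vox, IntegerVector dim,
                                   NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nn = (size_t)nx * ny * nz;
  std::vector<double> a(vox.begin(), vox.end()), tmp(nn);
  es_smooth3(a.data(), tmp.data(), nx, ny, nz, sigma[0], sigma[1], sigma[2]);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Central-difference gradient of a displacement field on its domain.
// field components ux,uy,uz in mm; spacing in mm. A voxel is valid when it
// and its six axial neighbours are inside the lattice and the domain.
// Returns grad (nx,ny,nz,9) with entry a + 3*b = dU_a/dx_b, plus validity.
// [[Rcpp::export]]
List displacement_gradient_cpp(NumericVector ux, NumericVector uy,
                               NumericVector uz, IntegerVector dim,
                               NumericVector spacing, IntegerVector domain) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nn = (size_t)nx * ny * nz;
  NumericVector grad(nn * 9);
  LogicalVector valid(nn);
  const size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  const double* U[3] = {ux.begin(), uy.begin(), uz.begin()};
  const size_t strides[3] = {sx, sy, sz};
  const double inv2[3] = {0.5 / spacing[0], 0.5 / spacing[1], 0.5 / spacing[2]};
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        size_t q = i + sy * j + sz * k;
        if (!domain[q]) continue;
        if (i < 1 || j < 1 || k < 1 || i > nx - 2 || j > ny - 2 || k > nz - 2)
          continue;
        bool ok = true;
        for (int ax = 0; ax < 3 && ok; ax++)
          if (!domain[q + strides[ax]] || !domain[q - strides[ax]]) ok = false;
        if (!ok) continue;
        valid[q] = true;
        for (int b = 0; b < 3; b++) {
          size_t st = strides[b];
          for (int a = 0; a < 3; a++)
            grad[q * 9 + a + 3 * b] = (U[a][q + st] - U[a][q - st]) * inv2[b];
        }
      }
  // reorder grad to (nx,ny,nz,9) lattice-major layout expected by R
  NumericVector gout(nn * 9);
  for (size_t q = 0; q < nn; q++)
    for (int c = 0; c < 9; c++) gout[q + nn * c] = grad[q * 9 + c];
  gout.attr("dim") = IntegerVector::create(nx, ny, nz, 9);
  valid.attr("dim") = dim;
  return List::create(_["grad"] = gout, _["valid"] = valid);
}
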