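#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "sampling.h"
#include "smoothing.h"
using namespace Rcpp;

// Level-set motion (intensity morphing) registration, demons-style
// discretization: at each iteration the moving image is warped by the current
// field, the residual against the fixed image drives a velocity along the
// warped-image gradient, the step is capped, and the accumulated field is
// Gaussian-smoothed. The field maps fixed-lattice points into moving space
// (pull-back convention), in mm.
// [[Rcpp::export]]
List level_set_cpp(NumericVector fixedv, NumericVector movingv,
                   IntegerVector dim, NumericVector spacing, int iterations,
                   double sigma_vox, double step_cap_vox, double eps,
                   double bg) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nn = (size_t)nx * ny * nz;
  // single-precision working buffers: the loop is memory-bound and the
  // ~1e-4 mm storage granularity is far below voxel scale
  std::vector<float> ux(nn, 0), uy(nn, 0), uz(nn, 0);
  std::vector<float> bux(nn, 0), buy(nn, 0), buz(nn, 0);
  std::vector<float> w(nn), tmp(nn);
  std::vector<float> fvv(fixedv.begin(), fixedv.end());
  std::vector<float> mvv(movingv.begin(), movingv.end());
  const float* fv = fvv.data();
  const float* mv = mvv.data();
  const size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  double cap_mm = step_cap_vox * std::min(spacing[0], std::min(spacing[1], spacing[2]));
  std::vector<double> trace;
  trace.reserve(iterations + 1);
  double best = R_PosInf;
  int best_iter = 0;

  auto warp_now = [&]() {
    size_t q = 0;
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++, q++)
          w[q] = es_sample_lin(mv, nx, ny, nz, i + ux[q] / spacing[0],
                               j + uy[q] / spacing[1], k + uz[q] / spacing[2],
                               bg);
  };
  auto msd_now = [&]() {
    double acc = 0;
    for (size_t q = 0; q < nn; q++) {
      double d = fv[q] - w[q];
      acc += d * d;
    }
    return acc / nn;
  };

  for (int it = 0; it < iterations; it++) {
    warp_now();
    double msd = msd_now();
    if (!std::isfinite(msd)) stop("non-finite update at iteration %d", it + 1);
    trace.push_back(msd);
    if (msd < best) {
      best = msd;
      best_iter = it;
      bux = ux; buy = uy; buz = uz;
    }
    // velocity = r * grad(w) / (|grad w|^2 + eps), capped, accumulated
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          size_t q = i + sy * j + sz * k;
          double gx, gy, gz;
          if (i == 0)           gx = (w[q + sx] - w[q]) / spacing[0];
          else if (i == nx - 1) gx = (w[q] - w[q - sx]) / spacing[0];
          else                  gx = (w[q + sx] - w[q - sx]) / (2 * spacing[0]);
          if (j == 0)           gy = (w[q + sy] - w[q]) / spacing[1];
          else if (j == ny - 1) gy = (w[q] - w[q - sy]) / spacing[1];
          else                  gy = (w[q + sy] - w[q - sy]) / (2 * spacing[1]);
          if (k == 0)           gz = (w[q + sz] - w[q]) / spacing[2];
          else if (k == nz - 1) gz = (w[q] - w[q - sz]) / spacing[2];
          else                  gz = (w[q + sz] - w[q - sz]) / (2 * spacing[2]);
          double g2 = gx * gx + gy * gy + gz * gz;
          double r = fv[q] - w[q];
          double f = r / (g2 + eps);
          double vx = f * gx, vy = f * gy, vz = f * gz;
          double vn = std::sqrt(vx * vx + vy * vy + vz * vz);
          if (vn > cap_mm) {
            double sc = cap_mm / vn;
            vx *= sc; vy *= sc; vz *= sc;
          }
          ux[q] += vx; uy[q] += vy; uz[q] += vz;
        }
    es_smooth3(ux.data(), tmp.data(), nx, ny, nz, sigma_vox, sigma_vox, sigma_vox);
    es_smooth3(uy.data(), tmp.data(), nx, ny, nz, sigma_vox, sigma_vox, sigma_vox);
    es_smooth3(uz.data(), tmp.data(), nx, ny, nz, sigma_vox, sigma_vox, sigma_vox);
  }
  warp_now();
  double final_msd = msd_now();
  trace.push_back(final_msd);
  bool reverted = false;
  if (iterations > 0 && final_msd > best) {
    // keep the best-metric field so the final MSD never exceeds the initial
    ux = bux; uy = buy; uz = buz;
    final_msd = best;
    reverted = true;
  }
  NumericVector U(nn * 3);
  std::copy(ux.begin(), ux.end(), U.begin());
  std::copy(uy.begin(), uy.end(), U.begin() + nn);
  std::copy(uz.begin(), uz.end(), U.begin() + 2 * nn);
  U.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return List::create(_["field"] = U, _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["final_msd"] = final_msd, _["reverted"] = reverted,
                      _["best_iter"] = best_iter + 1);
}
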