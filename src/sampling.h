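#ifndef EVARSTRAIN_SAMPLING_H
#define EVARSTRAIN_SAMPLING_H
#include <cmath>
#include <algorithm>

// Trilinear / nearest sampling on a column-major 3D lattice in continuous
// voxel coordinates. Positions outside the closed lattice hull return bg.
template <typename T>
static inline double es_sample_lin(const T* v, int nx, int ny, int nz,
                                   double x, double y, double z, double bg) {
  const double tol = 1e-6;  // absorb floating-point jitter at lattice edges
  if (x < -tol || y < -tol || z < -tol || x > nx - 1 + tol ||
      y > ny - 1 + tol || z > nz - 1 + tol)
    return bg;
  x = std::min(std::max(x, 0.0), (double)(nx - 1));
  y = std::min(std::max(y, 0.0), (double)(ny - 1));
  z = std::min(std::max(z, 0.0), (double)(nz - 1));
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  if (nx == 1) i0 = 0;
  if (ny == 1) j0 = 0;
  if (nz == 1) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
      k1 = std::min(k0 + 1, nz - 1);
  const size_t sy = nx, sz = (size_t)nx * ny;
  double c00 = v[i0 + j0 * sy + k0 * sz] * (1 - fx) + v[i1 + j0 * sy + k0 * sz] * fx;
  double c10 = v[i0 + j1 * sy + k0 * sz] * (1 - fx) + v[i1 + j1 * sy + k0 * sz] * fx;
  double c01 = v[i0 + j0 * sy + k1 * sz] * (1 - fx) + v[i1 + j0 * sy + k1 * sz] * fx;
  double c11 = v[i0 + j1 * sy + k1 * sz] * (1 - fx) + v[i1 + j1 * sy + k1 * sz] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

template <typename T>
static inline double es_sample_nn(const T* v, int nx, int ny, int nz,
                                  double x, double y, double z, double bg) {
  int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return bg;
  return v[i + (size_t)nx * (j + (size_t)ny * k)];
}
#endif
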