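#ifndef EVARSTRAIN_SMOOTHING_H
#define EVARSTRAIN_SMOOTHING_H
#include <vector>
#include <cmath>
#include <cstring>
#include <algorithm>

// Separable Gaussian smoothing with reflected boundaries, organized as
// contiguous-memory SAXPY passes (per-row for x/y, per-slice for z) so the
// compiler can vectorize the inner loops.

static inline int es_reflect(int p, int len) {
  if (p < 0) p = -p;
  if (p >= len) p = 2 * len - 2 - p;
  if (p < 0) p = 0;
  return p;
}

static inline void es_gauss_kernel(double sigma, std::vector<double>& k,
                                   int& rad) {
  rad = (int)std::ceil(3.0 * sigma);
  k.assign(2 * rad + 1, 0.0);
  double s = 0;
  for (int i = -rad; i <= rad; i++) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (auto& w : k) w /= s;
}

// smooth along x: per contiguous row
template <typename T>
static inline void es_smooth_x(T* a, T* tmp, int nx, int ny,
                               int nz, const std::vector<double>& k,
                               int rad) {
  size_t nrow = (size_t)ny * nz;
  for (size_t r = 0; r < nrow; r++) {
    T* row = a + r * nx;
    T* out = tmp + r * nx;
    std::memset(out, 0, sizeof(T) * nx);
    for (int d = -rad; d <= rad; d++) {
      double w = k[d + rad];
      int lo = std::max(0, -d), hi = std::min(nx, nx - d);
      for (int i = lo; i < hi; i++) out[i] += w * row[i + d];
      for (int i = 0; i < lo; i++) out[i] += w * row[es_reflect(i + d, nx)];
      for (int i = hi; i < nx; i++) out[i] += w * row[es_reflect(i + d, nx)];
    }
  }
  std::memcpy(a, tmp, sizeof(T) * nx * nrow);
}

// smooth along y: per z-slice, rows combined by SAXPY
template <typename T>
static inline void es_smooth_y(T* a, T* tmp, int nx, int ny,
                               int nz, const std::vector<double>& k,
                               int rad) {
  size_t sl = (size_t)nx * ny;
  for (int z = 0; z < nz; z++) {
    T* s = a + sl * z;
    T* o = tmp + sl * z;
    std::memset(o, 0, sizeof(T) * sl);
    for (int j = 0; j < ny; j++) {
      T* out = o + (size_t)nx * j;
      for (int d = -rad; d <= rad; d++) {
        const T* src = s + (size_t)nx * es_reflect(j + d, ny);
        double w = k[d + rad];
        for (int i = 0; i < nx; i++) out[i] += w * src[i];
      }
    }
  }
  std::memcpy(a, tmp, sizeof(T) * sl * nz);
}

// smooth along z: slices combined by SAXPY
template <typename T>
static inline void es_smooth_z(T* a, T* tmp, int nx, int ny,
                               int nz, const std::vector<double>& k,
                               int rad) {
  size_t sl = (size_t)nx * ny;
  for (int z = 0; z < nz; z++) {
    T* out = tmp + sl * z;
    std::memset(out, 0, sizeof(T) * sl);
    for (int d = -rad; d <= rad; d++) {
      const T* src = a + sl * es_reflect(z + d, nz);
      double w = k[d + rad];
      for (size_t i = 0; i < sl; i++) out[i] += w * src[i];
    }
  }
  std::memcpy(a, tmp, sizeof(T) * sl * nz);
}

template <typename T>
static inline void es_smooth3(T* a, T* tmp, int nx, int ny, int nz,
                              double sx, double sy, double sz) {
  std::vector<double> k;
  int rad;
  if (sx > 0) {
    es_gauss_kernel(sx, k, rad);
    es_smooth_x(a, tmp, nx, ny, nz, k, rad);
  }
  if (sy > 0) {
    es_gauss_kernel(sy, k, rad);
    es_smooth_y(a, tmp, nx, ny, nz, k, rad);
  }
  if (sz > 0) {
    es_gauss_kernel(sz, k, rad);
    es_smooth_z(a, tmp, nx, ny, nz, k, rad);
  }
}
#endif
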