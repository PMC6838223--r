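#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 26-connected component labelling by breadth-first search.
// [[Rcpp::export]]
List connected_components_cpp(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nn = (size_t)nx * ny * nz;
  IntegerVector labels(nn);
  std::vector<int> sizes;
  std::vector<size_t> stack;
  int lab = 0;
  for (size_t s = 0; s < nn; s++) {
    if (!mask[s] || labels[s]) continue;
    lab++;
    int count = 0;
    stack.clear();
    stack.push_back(s);
    labels[s] = lab;
    while (!stack.empty()) {
      size_t q = stack.back();
      stack.pop_back();
      count++;
      int i = q % nx, j = (q / nx) % ny, k = q / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t p = ii + (size_t)nx * (jj + (size_t)ny * kk);
            if (mask[p] && !labels[p]) {
              labels[p] = lab;
              stack.push_back(p);
            }
          }
    }
    sizes.push_back(count);
  }
  labels.attr("dim") = dim;
  return List::create(_["labels"] = labels,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}

// Adaptive region growing. The region starts as the 3x3x3 neighbourhood of
// the seed. Each iteration (1) estimates mu and sd over the current region
// (sd floored at 1 HU), then (2) flood-fills from the region across
// 26-connectivity, accepting every connected voxel whose intensity lies in
// [mu - k*sd, mu + k*sd]. Stops when the region reaches a fixed point or
// after max_iter interval updates.
// [[Rcpp::export]]
List region_grow_cpp(NumericVector vox, IntegerVector dim, IntegerVector seed,
                     double kmul, int max_iter) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nn = (size_t)nx * ny * nz;
  const double* v = vox.begin();
  std::vector<char> in(nn, 0);
  double sum = 0, sum2 = 0;
  long cnt = 0;
  // seed neighbourhood
  int si = seed[0], sj = seed[1], sk = seed[2];
  for (int dk = -1; dk <= 1; dk++)
    for (int dj = -1; dj <= 1; dj++)
      for (int di = -1; di <= 1; di++) {
        int ii = si + di, jj = sj + dj, kk = sk + dk;
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        size_t p = ii + (size_t)nx * (jj + (size_t)ny * kk);
        if (!in[p]) {
          in[p] = 1;
          sum += v[p];
          sum2 += v[p] * v[p];
          cnt++;
        }
      }
  std::vector<size_t> stack;
  int it = 0;
  for (it = 0; it < max_iter; it++) {
    double mu = sum / cnt;
    double var = sum2 / cnt - mu * mu;
    double sd = var > 0 ? std::sqrt(var) : 0;
    if (sd < 1.0) sd = 1.0;
    double lo = mu - kmul * sd, hi = mu + kmul * sd;
    // flood fill from the current region under the fixed interval
    stack.clear();
    for (size_t q = 0; q < nn; q++)
      if (in[q]) stack.push_back(q);
    long added = 0;
    while (!stack.empty()) {
      size_t q = stack.back();
      stack.pop_back();
      int i = q % nx, j = (q / nx) % ny, k = q / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                kk >= nz)
              continue;
            size_t p = ii + (size_t)nx * (jj + (size_t)ny * kk);
            if (!in[p] && v[p] >= lo && v[p] <= hi) {
              in[p] = 1;
              sum += v[p];
              sum2 += v[p] * v[p];
              cnt++;
              added++;
              stack.push_back(p);
            }
          }
    }
    if (added == 0) { it++; break; }
  }
  IntegerVector mask(nn);
  for (size_t q = 0; q < nn; q++) mask[q] = in[q] ? 1 : 0;
  mask.attr("dim") = dim;
  bool degenerate = (it == max_iter) || ((double)cnt / nn > 0.5);
  return List::create(_["mask"] = mask, _["iterations"] = it,
                      _["degenerate"] = degenerate, _["voxels"] = (double)cnt);
}

// Binary dilation with a cubic structuring element of given radius (voxels).
// [[Rcpp::export]]
IntegerVector dilate_cpp(IntegerVector mask, IntegerVector dim, int rad) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nn = (size_t)nx * ny * nz;
  IntegerVector out(nn);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        size_t q = i + (size_t)nx * (j + (size_t)ny * k);
        if (!mask[q]) continue;
        for (int dk = -rad; dk <= rad; dk++)
          for (int dj = -rad; dj <= rad; dj++)
            for (int di = -rad; di <= rad; di++) {
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              out[ii + (size_t)nx * (jj + (size_t)ny * kk)] = 1;
            }
      }
  out.attr("dim") = dim;
  return out;
}
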