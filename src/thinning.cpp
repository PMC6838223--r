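#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---- exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher),
// per-axis lower envelope with anisotropic spacing ----
static void edt_1d(std::vector<double>& f, std::vector<double>& d, double sp) {
  int n = f.size();
  std::vector<int> vtx(n);
  std::vector<double> zz(n + 1);
  int k = 0;
  vtx[0] = 0;
  zz[0] = -std::numeric_limits<double>::infinity();
  zz[1] = std::numeric_limits<double>::infinity();
  double sp2 = sp * sp;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      int p = vtx[k];
      s = ((f[q] + sp2 * q * q) - (f[p] + sp2 * p * p)) / (2.0 * sp2 * (q - p));
      if (s <= zz[k]) k--; else break;
    }
    k++;
    vtx[k] = q;
    zz[k] = s;
    zz[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (zz[k + 1] < q) k++;
    double dq = sp * (q - vtx[k]);
    d[q] = dq * dq + f[vtx[k]];
  }
}

// Squared EDT of a binary mask (distance from each foreground voxel to the
// nearest background voxel), spacing-aware; background voxels get 0.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(IntegerVector mask, IntegerVector dim,
                         NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nn = (size_t)nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> d(nn);
  for (size_t q = 0; q < nn; q++) d[q] = mask[q] ? INF : 0.0;
  std::vector<double> line, out;
  // x
  line.resize(nx); out.resize(nx);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      size_t base = (size_t)nx * (j + (size_t)ny * k);
      for (int i = 0; i < nx; i++) line[i] = d[base + i];
      edt_1d(line, out, spacing[0]);
      for (int i = 0; i < nx; i++) d[base + i] = out[i];
    }
  // y
  line.resize(ny); out.resize(ny);
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      size_t base = i + (size_t)nx * ny * (size_t)k;
      for (int j = 0; j < ny; j++) line[j] = d[base + (size_t)nx * j];
      edt_1d(line, out, spacing[1]);
      for (int j = 0; j < ny; j++) d[base + (size_t)nx * j] = out[j];
    }
  // z
  line.resize(nz); out.resize(nz);
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      size_t base = i + (size_t)nx * j;
      for (int k = 0; k < nz; k++) line[k] = d[base + (size_t)nx * ny * (size_t)k];
      edt_1d(line, out, spacing[2]);
      for (int k = 0; k < nz; k++) d[base + (size_t)nx * ny * (size_t)k] = out[k];
    }
  NumericVector res(d.begin(), d.end());
  res.attr("dim") = dim;
  return res;
}

// ---- topological simple-point test for (26,6) digital topology ----
// A voxel is simple iff exactly one 26-component of foreground in its
// punctured 3x3x3 neighbourhood, and exactly one 6-component of background
// in its 18-neighbourhood that touches a face neighbour.

static inline int off_idx(int di, int dj, int dk) {
  return (di + 1) + 3 * ((dj + 1) + 3 * (dk + 1));
}

static int count_fg26(const bool* nb) {
  // nb: 27 occupancy flags of the 3x3x3 cube, centre ignored
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  for (int s = 0; s < 27; s++) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    comps++;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int q = stack[--top];
      int qi = q % 3, qj = (q / 3) % 3, qk = q / 9;
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (!di && !dj && !dk) continue;
            int ii = qi + di, jj = qj + dj, kk = qk + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii > 2 || jj > 2 || kk > 2)
              continue;
            int p = ii + 3 * (jj + 3 * kk);
            if (p == 13 || !nb[p] || seen[p]) continue;
            seen[p] = true;
            stack[top++] = p;
          }
    }
  }
  return comps;
}

static int count_bg6(const bool* nb) {
  // 6-components of background within the 18-neighbourhood (exclude corners
  // and centre), counting only components containing a face neighbour.
  bool in18[27];
  for (int s = 0; s < 27; s++) {
    int di = s % 3 - 1, dj = (s / 3) % 3 - 1, dk = s / 9 - 1;
    int m = std::abs(di) + std::abs(dj) + std::abs(dk);
    in18[s] = (m == 1 || m == 2);
  }
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  for (int s = 0; s < 27; s++) {
    if (!in18[s] || nb[s] || seen[s]) continue;
    int di = s % 3 - 1, dj = (s / 3) % 3 - 1, dk = s / 9 - 1;
    if (std::abs(di) + std::abs(dj) + std::abs(dk) != 1) continue; // start at faces
    comps++;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int q = stack[--top];
      int qi = q % 3, qj = (q / 3) % 3, qk = q / 9;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int e = 0; e < 6; e++) {
        int ii = qi + d6[e][0], jj = qj + d6[e][1], kk = qk + d6[e][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii > 2 || jj > 2 || kk > 2) continue;
        int p = ii + 3 * (jj + 3 * kk);
        if (!in18[p] || nb[p] || seen[p]) continue;
        seen[p] = true;
        stack[top++] = p;
      }
    }
  }
  return comps;
}

// Distance-ordered homotopic thinning to a 1-voxel-wide curve skeleton.
// Simple points are removed in increasing distance-transform order; curve
// endpoints (<= 1 foreground 26-neighbour) are preserved.
// [[Rcpp::export]]
IntegerVector homotopic_thin_cpp(IntegerVector mask, IntegerVector dim,
                                 NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nn = (size_t)nx * ny * nz;
  NumericVector dist = edt_sq_cpp(mask, dim, spacing);
  std::vector<char> fg(nn);
  for (size_t q = 0; q < nn; q++) fg[q] = mask[q] ? 1 : 0;

  auto neighbors26 = [&](size_t q, int* out_n) {
    int i = q % nx, j = (q / nx) % ny, k = q / ((size_t)nx * ny);
    int cnt = 0;
    for (int dk = -1; dk <= 1; dk++)
      for (int dj = -1; dj <= 1; dj++)
        for (int di = -1; di <= 1; di++) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          size_t p = ii + (size_t)nx * (jj + (size_t)ny * kk);
          if (fg[p]) out_n[cnt++] = (int)p;
        }
    return cnt;
  };
  auto local_cube = [&](size_t q, bool* nb) {
    int i = q % nx, j = (q / nx) % ny, k = q / ((size_t)nx * ny);
    for (int dk = -1; dk <= 1; dk++)
      for (int dj = -1; dj <= 1; dj++)
        for (int di = -1; di <= 1; di++) {
          int s = off_idx(di, dj, dk);
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            nb[s] = false;
          else
            nb[s] = fg[ii + (size_t)nx * (jj + (size_t)ny * kk)] != 0;
        }
  };
  auto removable = [&](size_t q) {
    int nbrs[26];
    int deg = neighbors26(q, nbrs);
    if (deg <= 1) return false;  // endpoint or isolated: preserve
    bool nb[27];
    local_cube(q, nb);
    if (count_fg26(nb) != 1) return false;
    return count_bg6(nb) == 1;
  };

  typedef std::pair<double, size_t> PQE;
  std::priority_queue<PQE, std::vector<PQE>, std::greater<PQE> > pq;
  for (size_t q = 0; q < nn; q++)
    if (fg[q]) pq.push(PQE(dist[q], q));
  while (!pq.empty()) {
    size_t q = pq.top().second;
    pq.pop();
    if (!fg[q] || !removable(q)) continue;
    fg[q] = 0;
    int nbrs[26];
    int deg = neighbors26(q, nbrs);
    for (int e = 0; e < deg; e++) pq.push(PQE(dist[nbrs[e]], (size_t)nbrs[e]));
  }
  IntegerVector out(nn);
  for (size_t q = 0; q < nn; q++) out[q] = fg[q] ? 1 : 0;
  out.attr("dim") = dim;
  return out;
}
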