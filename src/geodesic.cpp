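#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Dijkstra geodesic distances over the 26-connected foreground voxels of a
// mask, with physical (mm) step weights. Returns per-voxel distance (Inf
// where unreachable or background) and the predecessor linear index
// (1-based; 0 for none) for path backtracking.
// [[Rcpp::export]]
List skeleton_geodesic_cpp(IntegerVector mask, IntegerVector dim,
                           NumericVector spacing, IntegerVector sources) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nn = (size_t)nx * ny * nz;
  NumericVector dist(nn, R_PosInf);
  IntegerVector prev(nn, 0);
  typedef std::pair<double, size_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int s = 0; s < sources.size(); s++) {
    int source = sources[s];
    if (source < 0 || (size_t)source >= nn || !mask[source])
      stop("source is not a foreground voxel");
    dist[source] = 0;
    pq.push(QE(0.0, (size_t)source));
  }
  while (!pq.empty()) {
    double dcur = pq.top().first;
    size_t q = pq.top().second;
    pq.pop();
    if (dcur > dist[q]) continue;
    int i = q % nx, j = (q / nx) % ny, k = q / ((size_t)nx * ny);
    for (int dk = -1; dk <= 1; dk++)
      for (int dj = -1; dj <= 1; dj++)
        for (int di = -1; di <= 1; di++) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          size_t p = ii + (size_t)nx * (jj + (size_t)ny * kk);
          if (!mask[p]) continue;
          double sx = di * spacing[0], sy = dj * spacing[1],
                 sz = dk * spacing[2];
          double w = std::sqrt(sx * sx + sy * sy + sz * sz);
          if (dist[q] + w < dist[p]) {
            dist[p] = dist[q] + w;
            prev[p] = (int)q + 1;
            pq.push(QE(dist[p], p));
          }
        }
  }
  return List::create(_["dist"] = dist, _["prev"] = prev);
}
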