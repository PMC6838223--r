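#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// C^3 septic smootherstep and compact axial bump, matching the R versions
static inline double ss(double t) {
  if (t <= 0) return 0.0;
  if (t >= 1) return 1.0;
  double t2 = t * t;
  return t2 * t2 * (35 - 84 * t + 70 * t2 - 20 * t2 * t);
}
static inline double gfun(double z, double z0, double L) {
  return ss(1.0 - std::fabs(z - z0) / L);
}

// Radial bulge displacement U = a g(z) h(r) w(dy/r) r_hat evaluated at pts.
// par = (a, cx, cy, z0, L, ra, rb, ulo, uhi, has_window)
// [[Rcpp::export]]
NumericMatrix bulge_u_cpp(NumericMatrix pts, NumericVector par) {
  int n = pts.nrow();
  NumericMatrix U(n, 3);
  double a = par[0], cx = par[1], cy = par[2], z0 = par[3], L = par[4],
         ra = par[5], rb = par[6], ulo = par[7], uhi = par[8];
  bool win = par[9] > 0.5;
  for (int q = 0; q < n; q++) {
    double dx = pts(q, 0) - cx, dy = pts(q, 1) - cy, z = pts(q, 2);
    double r = std::sqrt(dx * dx + dy * dy);
    if (r <= ra) continue;
    double g = gfun(z, z0, L);
    if (g <= 0) continue;
    double h = ss((r - ra) / (rb - ra));
    if (h <= 0) continue;
    double w = win ? ss((dy / r - ulo) / (uhi - ulo)) : 1.0;
    if (w <= 0) continue;
    double phi = a * g * h * w / r;
    U(q, 0) = phi * dx;
    U(q, 1) = phi * dy;
  }
  return U;
}

// Random smooth harmonic perturbation with the same compact envelope.
// env = (cx, cy, z0, L, ra, rb, ulo, uhi, has_window); per-harmonic vectors
// kz, ph, m, psv, eps, dir (1 radial, 2 axial, 3 azimuthal).
// [[Rcpp::export]]
NumericMatrix harmonics_u_cpp(NumericMatrix pts, NumericVector env,
                              NumericVector kz, NumericVector ph,
                              IntegerVector m, NumericVector psv,
                              NumericVector eps, IntegerVector dir) {
  int n = pts.nrow(), K = kz.size();
  NumericMatrix U(n, 3);
  double cx = env[0], cy = env[1], z0 = env[2], L = env[3], ra = env[4],
         rb = env[5], ulo = env[6], uhi = env[7];
  bool win = env[8] > 0.5;
  for (int q = 0; q < n; q++) {
    double dx = pts(q, 0) - cx, dy = pts(q, 1) - cy, z = pts(q, 2);
    double r = std::sqrt(dx * dx + dy * dy);
    if (r <= ra) continue;
    double g = gfun(z, z0, L);
    if (g <= 0) continue;
    double h = ss((r - ra) / (rb - ra));
    if (h <= 0) continue;
    double w = win ? ss((dy / r - ulo) / (uhi - ulo)) : 1.0;
    if (w <= 0) continue;
    double envv = g * h * w;
    double th = std::atan2(dy, dx);
    double nx = dx / r, ny = dy / r;
    double ux = 0, uy = 0, uz = 0;
    for (int k = 0; k < K; k++) {
      double s = eps[k] * envv * std::sin(kz[k] * (z - z0) + ph[k]) *
                 std::cos(m[k] * th + psv[k]);
      if (dir[k] == 1) { ux += s * nx; uy += s * ny; }
      else if (dir[k] == 2) uz += s;
      else { ux -= s * ny; uy += s * nx; }
    }
    U(q, 0) = ux; U(q, 1) = uy; U(q, 2) = uz;
  }
  return U;
}
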