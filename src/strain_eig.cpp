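#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Symmetric eigendecomposition of N voxelwise 3x3 tensors given as the six
// unique entries (c11, c21, c31, c22, c32, c33). Eigenvalues are returned in
// descending order; eigenvectors are sign-canonicalized so the component of
// largest absolute value is positive (ties broken by earliest axis).
// [[Rcpp::export]]
List eig_sym3_cpp(NumericMatrix C6) {
  int n = C6.nrow();
  NumericMatrix vals(n, 3);
  NumericMatrix vecs(n, 9); // columns of V stacked: v1 (3), v2 (3), v3 (3)
  arma::mat33 M;
  arma::vec3 ev;
  arma::mat33 V;
  for (int q = 0; q < n; q++) {
    M(0, 0) = C6(q, 0); M(1, 0) = C6(q, 1); M(2, 0) = C6(q, 2);
    M(0, 1) = C6(q, 1); M(1, 1) = C6(q, 3); M(2, 1) = C6(q, 4);
    M(0, 2) = C6(q, 2); M(1, 2) = C6(q, 4); M(2, 2) = C6(q, 5);
    arma::eig_sym(ev, V, M); // ascending
    for (int c = 0; c < 3; c++) {
      int src = 2 - c; // descending order
      vals(q, c) = ev(src);
      double v0 = V(0, src), v1 = V(1, src), v2 = V(2, src);
      double a0 = std::abs(v0), a1 = std::abs(v1), a2 = std::abs(v2);
      double lead = v0;
      if (a1 > a0 && a1 > a2) lead = v1;
      else if (a2 > a0 && a2 > a1) lead = v2;
      if (lead < 0) { v0 = -v0; v1 = -v1; v2 = -v2; }
      vecs(q, 3 * c) = v0;
      vecs(q, 3 * c + 1) = v1;
      vecs(q, 3 * c + 2) = v2;
    }
  }
  return List::create(_["values"] = vals, _["vectors"] = vecs);
}
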