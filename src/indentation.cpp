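// Indentation modulus of an anisotropic elastic half-space, indented along
// the +e3 axis of the supplied frame.  The surface Green's function of the
// half-space is obtained from the Barnett-Lothe integral: for an in-surface
// direction tau, the second-rank tensor
//   B(tau) = (1/pi) \int_0^pi [ (mm) - (mn)(nn)^{-1}(nm) ] dphi ,
// with (ab)_jk = a_i C_ijks b_s and (m, n) an orthonormal pair sweeping the
// plane perpendicular to tau, gives the surface displacement under a point
// force F as u = B^{-1} F / (2 pi r).  The equivalent indentation modulus of
// an axisymmetric indenter is then
//   M = 2 / < (B^{-1})_33 >_tau ,
// the angular average running over the surface directions.  For an isotropic
// material this reduces exactly to M = E / (1 - nu^2).  Both integrands are
// smooth and periodic, so periodic trapezoid quadrature converges spectrally.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

void mandel_to_full(const arma::mat& M, double C[3][3][3][3]) {
  static const int idx[6][2] = {{0,0},{1,1},{2,2},{1,2},{0,2},{0,1}};
  const double s2 = std::sqrt(2.0);
  const double w[6] = {1.0, 1.0, 1.0, s2, s2, s2};
  for (int I = 0; I < 6; ++I) {
    for (int J = 0; J < 6; ++J) {
      const double v = M(I, J) / (w[I] * w[J]);
      const int i = idx[I][0], j = idx[I][1], k = idx[J][0], l = idx[J][1];
      C[i][j][k][l] = v; C[j][i][k][l] = v;
      C[i][j][l][k] = v; C[j][i][l][k] = v;
    }
  }
}

// (ab)_jk = a_i C_ijks b_s
inline void ab_tensor(const double C[3][3][3][3], const double a[3],
                      const double b[3], arma::mat33& out) {
  for (int j = 0; j < 3; ++j) {
    for (int k = 0; k < 3; ++k) {
      double s = 0.0;
      for (int i = 0; i < 3; ++i)
        for (int l = 0; l < 3; ++l)
          s += a[i] * C[i][j][k][l] * b[l];
      out(j, k) = s;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".bl_modulus")]]
double bl_modulus(const arma::mat& C_mandel, int n_omega, int n_phi) {
  double C[3][3][3][3];
  mandel_to_full(C_mandel, C);

  arma::mat33 mm, mn, nn, nm, B, Binv;
  double acc = 0.0;
  const double e3[3] = {0.0, 0.0, 1.0};

  for (int io = 0; io < n_omega; ++io) {
    // B(tau) = B(-tau): omega runs over [0, pi)
    const double om = M_PI * io / n_omega;
    const double b[3] = {-std::sin(om), std::cos(om), 0.0}; // e3 x tau
    B.zeros();
    for (int ip = 0; ip < n_phi; ++ip) {
      // integrand is pi-periodic in phi
      const double ph = M_PI * ip / n_phi;
      const double cph = std::cos(ph), sph = std::sin(ph);
      const double m[3] = {cph * b[0], cph * b[1], sph};
      const double n[3] = {-sph * b[0], -sph * b[1], cph};
      ab_tensor(C, m, m, mm);
      ab_tensor(C, m, n, mn);
      ab_tensor(C, n, n, nn);
      ab_tensor(C, n, m, nm);
      B += mm - mn * arma::inv(nn) * nm;
    }
    B /= static_cast<double>(n_phi);
    Binv = arma::inv(B);
    acc += Binv(2, 2);
  }
  const double mean_compliance = acc / n_omega;
  return 2.0 / mean_compliance;
}

// Batch version: one modulus per supplied Mandel matrix (stacked in a cube).
// [[Rcpp::export(name = ".bl_modulus_batch")]]
arma::vec bl_modulus_batch(const arma::cube& C_stack, int n_omega, int n_phi) {
  arma::vec out(C_stack.n_slices);
  for (arma::uword s = 0; s < C_stack.n_slices; ++s)
    out(s) = bl_modulus(C_stack.slice(s), n_omega, n_phi);
  return out;
}
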