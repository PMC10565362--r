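// Per-element kernels for the compressible one-term Ogden law.
//
// Deformation gradients arrive as an N x 9 matrix, one element per row,
// packed row-major: (F11, F12, F13, F21, ..., F33).  All stress work is
// done in the principal frame of b = F F^T via a symmetric 3x3
// eigendecomposition, which handles coalescent stretches without special
// branches (the principal deviatoric Kirchhoff stresses are smooth in the
// stretches).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// NumericMatrix is column-major: index rows explicitly.
static inline arma::mat33 unpack3(const Rcpp::NumericMatrix& M, int e) {
  arma::mat33 F;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) F(i, j) = M(e, 3 * i + j);
  return F;
}

static inline void pack3(Rcpp::NumericMatrix& M, int e, const arma::mat33& A) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) M(e, 3 * i + j) = A(i, j);
}

// Principal deviatoric Kirchhoff stresses beta_i = lam_i dpsi_dev/dlam_i:
//   beta_i = (2 mu / alpha) * (lt_i^alpha - (lt_1^a + lt_2^a + lt_3^a)/3)
// with lt_i = J^(-1/3) lam_i.  The alpha -> 0 limit is 2 mu ln(lt_i).
static inline arma::vec3 dev_kirchhoff(const arma::vec3& lt,
                                       double mu, double alpha) {
  arma::vec3 beta;
  if (std::fabs(alpha) < 1e-6) {
    for (int i = 0; i < 3; ++i) beta(i) = 2.0 * mu * std::log(lt(i));
    beta -= arma::accu(beta) / 3.0;  // exact: sum log(lt) = 0 analytically
  } else {
    arma::vec3 p;
    for (int i = 0; i < 3; ++i) p(i) = std::pow(lt(i), alpha);
    double pm = arma::accu(p) / 3.0;
    for (int i = 0; i < 3; ++i) beta(i) = (2.0 * mu / alpha) * (p(i) - pm);
  }
  return beta;
}

// [[Rcpp::export]]
NumericVector ogden_energy_cpp(NumericMatrix Fm, double mu, double alpha,
                               double K) {
  const int n = Fm.nrow();
  NumericVector psi(n);
  for (int e = 0; e < n; ++e) {
    arma::mat33 F = unpack3(Fm, e);
    double J = arma::det(F);
    if (!(J > 0.0))
      stop("non-positive Jacobian (J = %g) in element %d", J, e + 1);
    arma::vec3 s;  // singular values of F = principal stretches
    if (!arma::svd(s, F))
      stop("singular value decomposition failed in element %d", e + 1);
    double Jm13 = std::pow(J, -1.0 / 3.0);
    double dev;
    if (std::fabs(alpha) < 1e-6) {
      dev = 0.0;
      for (int i = 0; i < 3; ++i) {
        double l = std::log(Jm13 * s(i));
        dev += mu * l * l;
      }
    } else {
      double sum = 0.0;
      for (int i = 0; i < 3; ++i) sum += std::pow(Jm13 * s(i), alpha);
      dev = 2.0 * mu / (alpha * alpha) * (sum - 3.0);
    }
    double lj = std::log(J);
    psi[e] = dev + 0.5 * K * lj * lj;
  }
  return psi;
}

// Cauchy stress, one element per row (packed like F; symmetric).
// [[Rcpp::export]]
NumericMatrix ogden_stress_cpp(NumericMatrix Fm, double mu, double alpha,
                               double K) {
  const int n = Fm.nrow();
  NumericMatrix out(n, 9);
  arma::vec3 eval;
  arma::mat33 evec;
  for (int e = 0; e < n; ++e) {
    arma::mat33 F = unpack3(Fm, e);
    double J = arma::det(F);
    if (!(J > 0.0))
      stop("non-positive Jacobian (J = %g) in element %d", J, e + 1);
    arma::mat33 b = F * F.t();
    if (!arma::eig_sym(eval, evec, b))
      stop("eigendecomposition failed in element %d", e + 1);
    arma::vec3 lt;
    double Jm13 = std::pow(J, -1.0 / 3.0);
    for (int i = 0; i < 3; ++i)
      lt(i) = Jm13 * std::sqrt(std::max(eval(i), 0.0));
    arma::vec3 beta = dev_kirchhoff(lt, mu, alpha);
    arma::mat33 sig(arma::fill::zeros);
    for (int i = 0; i < 3; ++i)
      sig += (beta(i) / J) * (evec.col(i) * evec.col(i).t());
    double pv = K * std::log(J) / J;
    sig(0, 0) += pv; sig(1, 1) += pv; sig(2, 2) += pv;
    pack3(out, e, sig);
  }
  return out;
}

// First Piola-Kirchhoff stress P = J sigma F^-T (reference-configuration
// nodal force assembly in the forward solver).
// [[Rcpp::export]]
NumericMatrix ogden_piola_cpp(NumericMatrix Fm, double mu, double alpha,
                              double K) {
  const int n = Fm.nrow();
  NumericMatrix out(n, 9);
  arma::vec3 eval;
  arma::mat33 evec;
  for (int e = 0; e < n; ++e) {
    arma::mat33 F = unpack3(Fm, e);
    double J = arma::det(F);
    if (!(J > 0.0))
      stop("non-positive Jacobian (J = %g) in element %d", J, e + 1);
    arma::mat33 b = F * F.t();
    if (!arma::eig_sym(eval, evec, b))
      stop("eigendecomposition failed in element %d", e + 1);
    arma::vec3 lt;
    double Jm13 = std::pow(J, -1.0 / 3.0);
    for (int i = 0; i < 3; ++i)
      lt(i) = Jm13 * std::sqrt(std::max(eval(i), 0.0));
    arma::vec3 beta = dev_kirchhoff(lt, mu, alpha);
    arma::mat33 tau(arma::fill::zeros);  // Kirchhoff stress J*sigma
    for (int i = 0; i < 3; ++i)
      tau += beta(i) * (evec.col(i) * evec.col(i).t());
    double pv = K * std::log(J);
    tau(0, 0) += pv; tau(1, 1) += pv; tau(2, 2) += pv;
    arma::mat33 P = tau * arma::inv(F).t();
    pack3(out, e, P);
  }
  return out;
}

// Eigenvalues (ascending) of symmetric 3x3 matrices, one per row.
// [[Rcpp::export]]
NumericMatrix sym_eig3_cpp(NumericMatrix Sm) {
  const int n = Sm.nrow();
  NumericMatrix out(n, 3);
  arma::vec3 eval;
  for (int e = 0; e < n; ++e) {
    arma::mat33 S = unpack3(Sm, e);
    S = 0.5 * (S + S.t());
    if (!arma::eig_sym(eval, S))
      stop("eigendecomposition failed in row %d", e + 1);
    out(e, 0) = eval(0); out(e, 1) = eval(1); out(e, 2) = eval(2);
  }
  return out;
}
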