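# One-term compressible Ogden constitutive model.
#
# psi = (2 mu / alpha^2) (lt1^a + lt2^a + lt3^a - 3) + (K/2) (ln J)^2
# with deviatoric principal stretches lt_i = J^(-1/3) lambda_i.  The
# volumetric potential is fixed so that the volumetric Cauchy stress is
# exactly sigma_V = K ln(J)/J I.  The alpha -> 0 limit (|alpha| < 1e-6)
# is taken analytically (Hencky-type deviatoric energy mu sum(ln lt)^2),
# so optimizers may cross alpha = 0 safely.

#' Ogden material parameters
#'
#' @param mu small-strain shear modulus, Pa (> 0).
#' @param alpha dimensionless strain-stiffening exponent (negative for
#'   brain tissue in most of the literature; the alpha -> 0 limit is
#'   handled analytically).
#' @param K bulk modulus, Pa (> 0).
#' @param mu_bounds,alpha_bounds,K_bounds identification bounds stored
#'   alongside the values; defaults bracket the soft-tissue literature
#'   (mu in 100 Pa..10 kPa, K in 10 kPa..1 MPa, alpha in -100..100).
#' @return an object of class `ogden_params`.
#' @export
ogden_params <- function(mu, alpha, K,
                         mu_bounds = c(100, 1e4),
                         alpha_bounds = c(-100, 100),
                         K_bounds = c(1e4, 1e6)) {
  if (!is.numeric(mu) || mu <= 0) config_error("`mu` must be > 0 (Pa)")
  if (!is.numeric(K) || K <= 0) config_error("`K` must be > 0 (Pa)")
  if (!is.numeric(alpha) || !is.finite(alpha)) config_error("`alpha` must be finite")
  structure(list(mu = as.numeric(mu), alpha = as.numeric(alpha), K = as.numeric(K),
                 bounds = list(mu = sort(mu_bounds), alpha = sort(alpha_bounds),
                               K = sort(K_bounds))),
            class = "ogden_params")
}

#' @export
print.ogden_params <- function(x, ...) {
  E_nu <- small_strain_moduli(x)
  cat(sprintf("Ogden parameters: mu = %.6g Pa, alpha = %.6g, K = %.6g Pa\n",
              x$mu, x$alpha, x$K))
  cat(sprintf("  small-strain equivalents: E = %.6g Pa, nu = %.6f\n",
              E_nu["E"], E_nu["nu"]))
  invisible(x)
}

#' Strain energy density of the Ogden model
#'
#' @param F 3x3 deformation gradient with det F > 0.
#' @param params an [ogden_params()].
#' @return strain energy density psi in J m^-3; zero at F = identity.
#' @export
strain_energy <- function(F, params) {
  stopifnot(inherits(params, "ogden_params"))
  F <- as.matrix(F)
  if (!all(dim(F) == c(3L, 3L))) config_error("`F` must be 3x3")
  as.numeric(ogden_energy_cpp(matrix(pack3(F), 1L), params$mu, params$alpha,
                              params$K))
}

#' Cauchy stress of the Ogden model
#'
#' The deviatoric part is computed in the principal frame of F F^T (the
#' principal deviatoric Kirchhoff stresses are smooth in the stretches, so
#' coalescent eigenvalues need no special branch); the volumetric part is
#' K ln(J)/J I.
#'
#' @param F 3x3 deformation gradient with det F > 0.
#' @param params an [ogden_params()].
#' @return an object of class `stress_state`: `sigma` (symmetric 3x3
#'   Cauchy stress, Pa), `psi` (strain energy density) and
#'   `principal_stretches_dev` (deviatoric principal stretches,
#'   descending).
#' @export
cauchy_stress <- function(F, params) {
  stopifnot(inherits(params, "ogden_params"))
  F <- as.matrix(F)
  if (!all(dim(F) == c(3L, 3L))) config_error("`F` must be 3x3")
  row <- matrix(pack3(F), 1L)
  sig <- unpack3(ogden_stress_cpp(row, params$mu, params$alpha, params$K)[1, ])
  sig <- (sig + t(sig)) / 2
  J <- det(F)
  lam <- svd(F, nu = 0, nv = 0)$d
  structure(list(sigma = sig,
                 psi = as.numeric(ogden_energy_cpp(row, params$mu,
                                                   params$alpha, params$K)),
                 principal_stretches_dev = J^(-1 / 3) * lam),
            class = "stress_state")
}

#' Small-strain moduli from Ogden parameters
#'
#' Standard isotropic conversions from the shear and bulk moduli:
#' E = 9 K mu / (3 K + mu), nu = (3 K - 2 mu) / (6 K + 2 mu).
#'
#' @param params an [ogden_params()], or a list with `mu` and `K`.
#' @return named numeric vector `c(E = ..., nu = ...)` (Pa, dimensionless).
#' @export
small_strain_moduli <- function(params) {
  mu <- params$mu; K <- params$K
  if (mu <= 0 || K <= 0) config_error("mu and K must be > 0")
  c(E = 9 * K * mu / (3 * K + mu), nu = (3 * K - 2 * mu) / (6 * K + 2 * mu))
}
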