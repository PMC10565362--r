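# Parameter-targeted virtual field generation.
#
# Recipe: fix every node on the unknown-traction boundary, apply a body
# load much smaller than gravity (default 0.001 m s^-2) so deformations
# are small, solve once at the base parameters, re-solve with each
# material parameter perturbed in turn, and subtract the base field.
# The mu- and K-sensitivity fields come from the linear small-strain
# solver (alpha has no linear-regime footprint); the alpha field is the
# difference of two weakly nonlinear solves at the small load.  Each
# field is normalized to unit maximum nodal magnitude (the equilibrium
# gap is scale-invariant, so this only conditions the powers); a
# perturbation that produces no change is flagged degenerate rather than
# silently normalized.

#' Generate the three parameter-targeted virtual fields
#'
#' @param mesh a [tet_mesh()].
#' @param base_params an [ogden_params()]: the "convenient" generation
#'   parameters (need not equal the true tissue parameters).
#' @param body_dir direction of the small generation body load.
#' @param body_mag magnitude of the generation load, m s^-2 (default
#'   0.001, well below gravity so the generation regime is small-strain).
#' @param perturb list with `mu` and `K` multiplicative factors (default
#'   2) and `dalpha` additive shift (default -10).
#' @param fixed node set where the fields must vanish (default: all
#'   boundary nodes).
#' @param newton_tol Newton tolerance for the two weakly nonlinear
#'   alpha-field solves.  The alpha sensitivity is a small difference of
#'   two solutions (~1e-6 of the base field), so this must sit well below
#'   it; 1e-8 is below the signal but above the stress-evaluation noise
#'   floor at the tiny generation strains (~1e-9).
#' @param ops optional precomputed [mesh_operators()].
#' @return list of three [virtual_field()]s labelled `"mu"`, `"alpha"`,
#'   `"K"`; a degenerate field carries `degenerate = TRUE`.
#' @export
generate_sensitivity_fields <- function(mesh, base_params,
                                        body_dir = c(0, 0, -1),
                                        body_mag = 0.001,
                                        perturb = list(mu = 2, K = 2, dalpha = -10),
                                        fixed = mesh$boundary_nodes,
                                        newton_tol = 1e-8,
                                        ops = mesh_operators(mesh)) {
  body_dir <- as.numeric(body_dir)
  nb <- sqrt(sum(body_dir^2))
  if (nb == 0) config_error("`body_dir` must be non-zero")
  b <- body_dir / nb * body_mag

  base_lin <- solve_fixed_boundary(mesh, base_params, b, fixed = fixed, ops = ops)

  p_mu <- base_params; p_mu$mu <- base_params$mu * perturb$mu
  p_K <- base_params; p_K$K <- base_params$K * perturb$K
  d_mu <- solve_fixed_boundary(mesh, p_mu, b, fixed = fixed, ops = ops) - base_lin
  d_K <- solve_fixed_boundary(mesh, p_K, b, fixed = fixed, ops = ops) - base_lin

  p_a <- base_params; p_a$alpha <- base_params$alpha + perturb$dalpha
  base_nl <- forward_solve(mesh, base_params, b, fixed = fixed,
                           tol = newton_tol, ops = ops)$u
  d_a <- forward_solve(mesh, p_a, b, fixed = fixed,
                       tol = newton_tol, ops = ops)$u - base_nl

  ref_mag <- max(sqrt(rowSums(base_lin^2)), 1e-300)
  mk <- function(d, label) {
    mx <- max(sqrt(rowSums(d^2)))
    if (mx < 1e-12 * ref_mag) {
      vf <- virtual_field(mesh, d, label = label, ops = ops,
                          zero_set = fixed, check = FALSE)
      vf$degenerate <- TRUE
      warning(sprintf("virtual field '%s' is degenerate (zero sensitivity)", label))
      return(vf)
    }
    virtual_field(mesh, d / mx, label = label, ops = ops, zero_set = fixed)
  }
  list(mu = mk(d_mu, "mu"), alpha = mk(d_a, "alpha"), K = mk(d_K, "K"))
}
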