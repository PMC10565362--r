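# The virtual-power equilibrium gap.
#
# For a virtual velocity field v* with precomputed reference gradients
# G* = dv*/dX, the spatial gradient in the measured current configuration
# is grad v* = G* F^-1 (F the measured deformation gradient), the virtual
# rate of deformation is its symmetric part, and the one-point quadrature
# (exact on constant-strain tetrahedra) gives
#   P_int = sum_e (sigma : D*) J V0_e
#   P_ext = sum_e rho V0_e b . v*(centroid)
# The acceleration and surface-traction terms of the weak form are
# compiled out: the body load is static and virtual fields vanish on the
# boundaries with unknown tractions.

#' Construct a virtual velocity field
#'
#' @param mesh the [tet_mesh()] the field lives on.
#' @param v N x 3 matrix of nodal virtual velocities (arbitrary units).
#' @param label which parameter the field targets (informational).
#' @param ops optional precomputed [mesh_operators()].
#' @param zero_set node indices on which the field must vanish (default:
#'   the mesh boundary nodes, the surfaces with unknown tractions).
#' @param check if `TRUE`, error when the field is non-zero on `zero_set`.
#' @return object of class `virtual_field` with per-element reference
#'   gradients `G` (M x 9 packed) precomputed.
#' @export
virtual_field <- function(mesh, v, label = "", ops = mesh_operators(mesh),
                          zero_set = mesh$boundary_nodes, check = TRUE) {
  v <- check_field(v, mesh)
  if (check && length(zero_set)) {
    mx <- max(abs(v[zero_set, ]))
    ref <- max(abs(v), 1e-300)
    if (mx > 1e-9 * ref)
      config_error("virtual field is non-zero on its zero-traction boundary (max %g)", mx)
  }
  structure(list(v = v, G = batch_gradient(ops, v), label = label,
                 degenerate = FALSE),
            class = "virtual_field")
}

#' Spatial gradient of a virtual velocity in the measured configuration
#'
#' grad v* = G* F^-1; when the virtual field equals the measured
#' displacement field this reduces to (F - I) F^-1.
#'
#' @param G_star 3x3 reference gradient dv*/dX of the virtual field.
#' @param F 3x3 measured deformation gradient (det F > 0).
#' @return 3x3 spatial gradient.
#' @export
virtual_velocity_gradient <- function(G_star, F) {
  J <- det(F)
  if (!is.finite(J) || abs(J) < 1e-300) numeric_error("singular deformation gradient")
  G_star %*% solve(F)
}

#' Virtual rate of deformation (symmetric part of the spatial gradient)
#'
#' @param grad_v_star 3x3 spatial virtual velocity gradient.
#' @return symmetric 3x3 tensor; a pure spin maps to zero.
#' @export
rate_of_deformation <- function(grad_v_star) {
  (grad_v_star + t(grad_v_star)) / 2
}

#' Internal virtual power
#'
#' One-point quadrature of sigma : D* over the deformed volume:
#' sum over elements of (sigma : D*) J V0, with sigma the Ogden Cauchy
#' stress at the element's measured deformation gradient.
#'
#' @param mesh a [tet_mesh()].
#' @param disp measured N x 3 displacement field (metres).
#' @param vfield a [virtual_field()].
#' @param params an [ogden_params()].
#' @param ops optional precomputed [mesh_operators()].
#' @return scalar internal virtual power.
#' @export
internal_power <- function(mesh, disp, vfield, params,
                           ops = mesh_operators(mesh)) {
  disp <- check_field(disp, mesh)
  kin <- batch_kinematics(ops, disp)
  sig <- ogden_stress_cpp(kin$F, params$mu, params$alpha, params$K)
  Dst <- sym3_batch(mul3_batch(vfield$G, kin$Finv))
  sum(rowSums(sig * Dst) * kin$J * ops$V0)
}

#' External virtual power of a body force
#'
#' sum over elements of rho V0 b . v*(centroid); the centroid value of a
#' linear field is the mean of its four nodal values, and the deformed
#' volume factors cancel against the deformed density exactly.
#'
#' @param mesh a [tet_mesh()] (carries the density).
#' @param vfield a [virtual_field()].
#' @param body_force_b body force vector, m s^-2 (e.g. `c(0, 0, -9.81)`).
#' @param ops optional precomputed [mesh_operators()].
#' @return scalar external virtual power.
#' @export
external_power <- function(mesh, vfield, body_force_b,
                           ops = mesh_operators(mesh)) {
  b <- as.numeric(body_force_b)
  if (length(b) != 3L || any(!is.finite(b)))
    config_error("`body_force_b` must be a finite 3-vector")
  el <- ops$elements
  acc <- 0
  for (i in 1:3) {
    vbar <- (vfield$v[el[, 1L], i] + vfield$v[el[, 2L], i] +
             vfield$v[el[, 3L], i] + vfield$v[el[, 4L], i]) / 4
    acc <- acc + b[i] * sum(vbar * ops$V0)
  }
  mesh$density * acc
}

#' Normalized equilibrium gap of one virtual field
#'
#' @param P_int,P_ext internal and external virtual power.
#' @return signed relative gap (P_int - P_ext) / P_ext.
#' @export
field_error <- function(P_int, P_ext) {
  if (!is.finite(P_ext) || P_ext == 0)
    numeric_error("external virtual power is zero; cannot normalize the gap")
  (P_int - P_ext) / P_ext
}

#' Total virtual-power error (Pythagorean sum over the three fields)
#'
#' @param errors numeric vector of three per-field errors.
#' @return Euclidean norm of the error vector.
#' @export
total_error <- function(errors) {
  if (length(errors) != 3L) config_error("`errors` must have length 3")
  sqrt(sum(errors^2))
}

#' Self-consistency check of a forward solution
#'
#' Uses a converged forward-solver displacement simultaneously as the
#' measured field and the virtual field; the relative gap
#' |P_int - P_ext| / |P_ext| bounds the combined discretization/solver
#' error of the model that produced the field (insufficient refinement or
#' loose solver tolerances would bias an identification).
#'
#' @param forward_solution a [forward_solve()] result.
#' @param params the parameters of the solve (defaults to those stored).
#' @param b the body force of the solve (defaults to that stored).
#' @return relative gap (0 by convention for the zero-load solution).
#' @export
self_consistency_check <- function(forward_solution,
                                   params = forward_solution$params,
                                   b = forward_solution$b) {
  fs <- forward_solution
  if (!isTRUE(fs$converged))
    numeric_error("forward solution did not converge; self-consistency undefined")
  ops <- fs$ops
  vf <- virtual_field(fs$mesh, fs$u, label = "self", ops = ops,
                      zero_set = fs$fixed, check = FALSE)
  P_ext <- external_power(fs$mesh, vf, b, ops)
  P_int <- internal_power(fs$mesh, fs$u, vf, params, ops)
  if (P_ext == 0 && P_int == 0) return(0)
  abs(P_int - P_ext) / abs(P_ext)
}
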