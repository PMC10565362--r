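# Synthetic ground-truth data: homogeneous-deformation fixtures, canned
# recovery bundles (forward solve + virtual fields on the same mesh),
# and measurement-noise emulation.

#' Homogeneous-deformation fixture
#'
#' A cube mesh with the exact affine field u = (F_target - I) X at every
#' node, so every element's computed deformation gradient equals
#' `F_target` to machine precision (linear tetrahedra are exact for
#' affine maps).
#'
#' @param F_target 3x3 target deformation gradient, det > 0.
#' @param n cube grid divisions (default 2).
#' @param edge cube edge, metres.
#' @return list with `mesh` and `disp`.
#' @export
homogeneous_fixture <- function(F_target, n = 2L, edge = 0.1) {
  F_target <- as.matrix(F_target)
  if (!all(dim(F_target) == c(3L, 3L)) || det(F_target) <= 0)
    config_error("`F_target` must be 3x3 with positive determinant")
  mesh <- cube_mesh(n = n, edge = edge)
  disp <- mesh$nodes %*% t(F_target - diag(3))
  list(mesh = mesh, disp = disp)
}

#' Measurement-noise specification
#'
#' @param rms target root-mean-square amplitude over all components,
#'   metres (the stated levels are 0.25, 0.5 and 1 micrometre).
#' @param kind `"iid_gaussian"`: independent N(0, rms^2) per component;
#'   `"smooth_field"`: a Gaussian-correlated random field rescaled to the
#'   requested RMS, emulating spatially smooth registration error.
#' @param correlation_length correlation length of the smooth kind,
#'   metres.
#' @param seed RNG seed fixing the realization (`NULL`: use the current
#'   RNG stream).
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(rms, kind = c("iid_gaussian", "smooth_field"),
                       correlation_length = 0.02, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(rms) || rms < 0) config_error("`rms` must be >= 0")
  if (kind == "smooth_field" && correlation_length <= 0)
    config_error("`correlation_length` must be > 0")
  structure(list(rms = rms, kind = kind,
                 correlation_length = correlation_length, seed = seed),
            class = "noise_spec")
}

#' Add synthetic measurement noise to a displacement field
#'
#' @param disp N x 3 displacement matrix (metres).
#' @param spec a [noise_spec()].
#' @param nodes node coordinates (needed for the smooth kind only).
#' @return the perturbed field; identical to `disp` when `rms = 0`.
#' @export
add_noise <- function(disp, spec, nodes = NULL) {
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$rms == 0) return(disp)
  n <- nrow(disp)
  with_seed(spec$seed, {
    if (spec$kind == "iid_gaussian") {
      disp + matrix(rnorm(3L * n, sd = spec$rms), n, 3L)
    } else {
      if (is.null(nodes)) config_error("smooth noise needs node coordinates")
      raw <- matrix(rnorm(3L * n), n, 3L)
      d2 <- as.matrix(dist(nodes))^2
      W <- exp(-d2 / (2 * spec$correlation_length^2))
      W <- W / rowSums(W)
      sm <- W %*% raw
      sm <- sm * spec$rms / sqrt(mean(sm^2))  # rescale to the requested RMS
      disp + sm
    }
  })
}

#' Build a ground-truth recovery bundle
#'
#' Forward-solves a canned fixture at the true parameters, generates the
#' three sensitivity virtual fields on the same mesh, optionally injects
#' noise, and returns the identification bundle together with the truth.
#'
#' @param fixture `"cube"` (edge 0.1 m, fully fixed boundary) or
#'   `"thick_shell_ellipsoid"` (fixed outer surface, traction-free inner
#'   cavity, mimicking skull confinement).
#' @param params_true the ground-truth [ogden_params()].
#' @param noise optional [noise_spec()] applied to the solved field.
#' @param n mesh divisions (default 6: the 1296-element cube fixture).
#' @param b body force, m s^-2 (default full gravity along -z).
#' @param density tissue density, kg m^-3.
#' @param vf_params parameters used to *generate* the virtual fields
#'   (defaults to `params_true`; any convenient values work).
#' @return list with `bundle` ([data_bundle()]), `params_true`, `forward`
#'   (the [forward_solve()] result) and `fields`.
#' @export
make_recovery_bundle <- function(fixture = c("cube", "thick_shell_ellipsoid"),
                                 params_true, noise = NULL, n = 6L,
                                 b = c(0, 0, -9.81), density = 1040,
                                 vf_params = params_true) {
  fixture <- match.arg(fixture)
  if (fixture == "cube") {
    mesh <- cube_mesh(n = n, edge = 0.1, density = density)
    fixed <- mesh$boundary_nodes
  } else {
    mesh <- shell_ellipsoid_mesh(n = max(4L, 2L * (n %/% 2L)), density = density)
    fixed <- attr(mesh, "outer_nodes")
  }
  ops <- mesh_operators(mesh)
  fwd <- forward_solve(mesh, params_true, b = b, fixed = fixed, ops = ops)
  disp <- fwd$u
  if (!is.null(noise)) disp <- add_noise(disp, noise, nodes = mesh$nodes)
  fields <- generate_sensitivity_fields(mesh, vf_params, fixed = fixed, ops = ops)
  bundle <- data_bundle(mesh, disp, fields, b = b, ops = ops)
  list(bundle = bundle, params_true = params_true, forward = fwd,
       fields = fields)
}
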