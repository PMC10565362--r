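# The identification data bundle: mesh + measured displacement + virtual
# fields + load, with everything that does not depend on the material
# parameters precomputed once (deformation gradients, their inverses and
# determinants, the spatial virtual rates of deformation, the external
# powers).  evaluate_params() is then a pure, fast function of the
# parameters: one batch stress evaluation and three weighted sums.

#' Build an identification bundle
#'
#' @param mesh a [tet_mesh()].
#' @param disp measured N x 3 displacement field (metres).
#' @param fields list of three [virtual_field()]s (order mu, alpha, K by
#'   convention).
#' @param b body force vector, m s^-2.  The paper-level caveat applies:
#'   for posture-inversion data the displacement corresponds to a load
#'   *change*, so the magnitude (g vs 2g) is the caller's explicit choice
#'   and has no default here.
#' @param ops optional precomputed [mesh_operators()].
#' @return object of class `data_bundle` with per-element caches.
#' @export
data_bundle <- function(mesh, disp, fields, b, ops = mesh_operators(mesh)) {
  disp <- check_field(disp, mesh)
  if (length(fields) != 3L || !all(vapply(fields, inherits, TRUE, "virtual_field")))
    config_error("`fields` must be a list of three virtual_field objects")
  b <- as.numeric(b)
  if (length(b) != 3L || any(!is.finite(b)))
    config_error("`b` must be a finite 3-vector (no default: see ?data_bundle)")
  kin <- batch_kinematics(ops, disp)  # reports J <= 0 once, at build time
  Dstar <- lapply(fields, function(vf) sym3_batch(mul3_batch(vf$G, kin$Finv)))
  P_ext <- vapply(fields, function(vf) external_power(mesh, vf, b, ops), 0)
  if (any(P_ext == 0))
    numeric_error("external virtual power is zero for field(s) %s",
                  paste(which(P_ext == 0), collapse = ", "))
  structure(list(mesh = mesh, disp = disp, fields = fields, b = b, ops = ops,
                 F = kin$F, J = kin$J, JV0 = kin$J * ops$V0,
                 Dstar = Dstar, P_ext = P_ext),
            class = "data_bundle")
}

#' Evaluate the virtual-power errors for a parameter set
#'
#' Pure function of the parameters given the bundle (concurrent
#' evaluations do not interact); costs one batch stress evaluation.
#'
#' @param params an [ogden_params()] (or list with mu, alpha, K).
#' @param bundle a [data_bundle()].
#' @return list with `errors` (three per-field gaps), `total` (their
#'   Euclidean norm), `P_int`, `P_ext`.
#' @export
evaluate_params <- function(params, bundle) {
  sig <- ogden_stress_cpp(bundle$F, params$mu, params$alpha, params$K)
  P_int <- vapply(bundle$Dstar, function(D)
    sum(rowSums(sig * D) * bundle$JV0), 0)
  errors <- (P_int - bundle$P_ext) / bundle$P_ext
  list(errors = unname(errors), total = total_error(errors),
       P_int = unname(P_int), P_ext = unname(bundle$P_ext))
}

#' Per-element stress statistics at a parameter set
#'
#' Cauchy stress in every element at the measured deformation; reports
#' the maximum-shear measure tau_max = (sigma_1 - sigma_3)/2 and the mean
#' (triaxial) stress tr(sigma)/3 with their percentiles and extrema.
#' Both conventions are configurable because neither is standardised in
#' the reporting literature.
#'
#' @param params an [ogden_params()].
#' @param bundle a [data_bundle()].
#' @param shear_prob percentile reported for the shear measure (default
#'   0.95).
#' @param mean_probs percentiles reported for the mean stress (default
#'   2.5% and 97.5%).
#' @param shear_measure `"max_shear"` (default) or `"von_mises"`.
#' @return list with `shear` (percentile, max), `mean_stress`
#'   (percentiles, range) and the per-element vectors.
#' @export
stress_statistics <- function(params, bundle, shear_prob = 0.95,
                              mean_probs = c(0.025, 0.975),
                              shear_measure = c("max_shear", "von_mises")) {
  shear_measure <- match.arg(shear_measure)
  sig <- ogden_stress_cpp(bundle$F, params$mu, params$alpha, params$K)
  ev <- sym_eig3_cpp(sig)  # ascending principal stresses
  shear <- switch(shear_measure,
    max_shear = (ev[, 3] - ev[, 1]) / 2,
    von_mises = sqrt(((ev[, 1] - ev[, 2])^2 + (ev[, 2] - ev[, 3])^2 +
                      (ev[, 3] - ev[, 1])^2) / 2))
  mean_stress <- (ev[, 1] + ev[, 2] + ev[, 3]) / 3
  list(shear = list(percentile = unname(quantile(shear, shear_prob)),
                    prob = shear_prob, max = max(shear)),
       mean_stress = list(percentiles = unname(quantile(mean_stress, mean_probs)),
                          probs = mean_probs,
                          min = min(mean_stress), max = max(mean_stress)),
       shear_measure = shear_measure,
       per_element = list(shear = shear, mean_stress = mean_stress))
}
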