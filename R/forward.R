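# Total-Lagrangian nonlinear forward solver (synthetic-data generator).
#
# Newton-Raphson on the reference-configuration weak form with the same
# compressible Ogden law as the constitutive module: nodal internal
# forces f_a = V0 P dN_a/dX with P = J sigma F^-T, a consistent body
# load rho V0 b / 4 per vertex, a numerically differentiated consistent
# tangent (central differences on the element-local displacements,
# assembled sparse), and load stepping with halving when a full-load
# Newton solve fails.  Used only to manufacture verification data; it is
# deliberately independent of the virtual-power path it validates.

#' Element-local internal forces from packed deformation gradients
#' @noRd
element_internal_forces <- function(ops, Fm, params) {
  P <- ogden_piola_cpp(Fm, params$mu, params$alpha, params$K)
  fe <- matrix(0, ops$n_elements, 12L)
  for (a in 1:4) for (i in 1:3) {
    acc <- P[, pack_idx(i, 1L)] * ops$G[, (a - 1L) * 3L + 1L] +
           P[, pack_idx(i, 2L)] * ops$G[, (a - 1L) * 3L + 2L] +
           P[, pack_idx(i, 3L)] * ops$G[, (a - 1L) * 3L + 3L]
    fe[, (a - 1L) * 3L + i] <- ops$V0 * acc
  }
  fe
}

#' Assemble global nodal internal force vector (3N, node-major dofs)
#' @noRd
global_internal_forces <- function(ops, disp, params) {
  Fm <- batch_gradient(ops, disp, add_identity = TRUE)
  J <- det3_batch(Fm)
  if (any(J <= 0)) return(NULL)  # inverted element: caller halves the step
  fe <- element_internal_forces(ops, Fm, params)
  f <- matrix(0, ops$n_nodes, 3L)
  for (i in 1:3) {
    W <- fe[, c(i, 3L + i, 6L + i, 9L + i), drop = FALSE]
    f[, i] <- as.numeric(ops$scatter %*% as.vector(W))
  }
  as.vector(t(f))
}

#' Numerically differentiated consistent tangent (sparse 3N x 3N)
#'
#' Perturbing element-local dof (a, i) by +/- h changes only that
#' element's F by +/- h e_i (dN_a/dX)^T, so all element tangent columns
#' are obtained from 24 batch stress evaluations.
#' @noRd
tangent_matrix <- function(ops, Fm, params, h) {
  m <- ops$n_elements
  x <- numeric(144L * m)
  for (a in 1:4) for (i in 1:3) {
    p <- (a - 1L) * 3L + i   # trial dof
    Fp <- Fm; Fmn <- Fm
    for (J in 1:3) {
      k <- pack_idx(i, J); g <- ops$G[, (a - 1L) * 3L + J]
      Fp[, k] <- Fm[, k] + h * g
      Fmn[, k] <- Fm[, k] - h * g
    }
    dfe <- (element_internal_forces(ops, Fp, params) -
            element_internal_forces(ops, Fmn, params)) / (2 * h)
    for (q in 1:12) {
      k <- (p - 1L) * 12L + q
      x[((k - 1L) * m + 1L):(k * m)] <- dfe[, q]
    }
  }
  Matrix::sparseMatrix(i = ops$asm_i, j = ops$asm_j, x = x,
                       dims = c(3L * ops$n_nodes, 3L * ops$n_nodes))
}

#' Nonlinear forward solve under a body force
#'
#' @param mesh a [tet_mesh()].
#' @param params an [ogden_params()].
#' @param b body force vector, m s^-2 (default gravity along -z).
#' @param fixed node indices with prescribed displacement (default: all
#'   boundary nodes; must be non-empty).
#' @param fixed_values optional prescribed displacements on `fixed`
#'   (length(fixed) x 3, metres); zero if `NULL`.
#' @param tol relative residual tolerance (default 1e-9).
#' @param max_iter Newton iterations per load step (default 25).
#' @param max_halvings load-step halvings before giving up (default 8).
#' @param u0 optional initial guess (N x 3).
#' @param ops optional precomputed [mesh_operators()].
#' @return object of class `forward_solution`: `u` (N x 3, metres),
#'   `converged`, `residual` (final relative norm), `iterations` (total
#'   Newton count), `J_range`, plus the mesh/params/load for downstream
#'   checks.
#' @export
forward_solve <- function(mesh, params, b = c(0, 0, -9.81),
                          fixed = mesh$boundary_nodes, fixed_values = NULL,
                          tol = 1e-9, max_iter = 25L, max_halvings = 8L,
                          u0 = NULL, ops = mesh_operators(mesh)) {
  b <- as.numeric(b)
  fixed <- sort(unique(as.integer(fixed)))
  if (!length(fixed)) config_error("fixed set is empty: rigid modes unconstrained")
  n <- ops$n_nodes
  fixed_dofs <- as.vector(t(outer(3L * (fixed - 1L), 1:3, `+`)))
  free <- setdiff(seq_len(3L * n), fixed_dofs)
  fext_full <- as.vector(t(body_force_vector(mesh, b, ops)))
  h <- 1e-7 * ops$char_length  # strain perturbation ~1e-7 for the FD tangent

  uvec <- if (is.null(u0)) numeric(3L * n) else as.vector(t(check_field(u0, mesh)))
  set_dirichlet <- function(uv, s) {
    if (is.null(fixed_values)) uv[fixed_dofs] <- 0
    else uv[fixed_dofs] <- s * as.vector(t(as.matrix(fixed_values)))
    uv
  }
  total_iters <- 0L
  final_res <- NA_real_

  newton <- function(uv, s) {
    fint <- global_internal_forces(ops, matrix(uv, n, 3L, byrow = TRUE), params)
    if (is.null(fint)) return(list(ok = FALSE, u = uv))
    r <- fint[free] - s * fext_full[free]
    ref <- max(sqrt(sum((s * fext_full[free])^2)), sqrt(sum(r^2)), 1e-300)
    for (it in seq_len(max_iter)) {
      rn <- sqrt(sum(r^2))
      final_res <<- rn / ref
      if (rn <= tol * ref) return(list(ok = TRUE, u = uv))
      total_iters <<- total_iters + 1L
      Fm <- batch_gradient(ops, matrix(uv, n, 3L, byrow = TRUE),
                           add_identity = TRUE)
      Kt <- tangent_matrix(ops, Fm, params, h)
      du <- tryCatch(as.numeric(Matrix::solve(Kt[free, free], -r)),
                     error = function(e) NULL)
      if (is.null(du)) return(list(ok = FALSE, u = uv))
      # step halving on element inversion
      step <- 1
      repeat {
        utry <- uv; utry[free] <- uv[free] + step * du
        fint <- global_internal_forces(ops, matrix(utry, n, 3L, byrow = TRUE),
                                       params)
        if (!is.null(fint)) break
        step <- step / 2
        if (step < 1e-3) return(list(ok = FALSE, u = uv))
      }
      uv <- utry
      r <- fint[free] - s * fext_full[free]
    }
    rn <- sqrt(sum(r^2)); final_res <<- rn / ref
    list(ok = rn <= tol * ref, u = uv)
  }

  # load ramp with halving
  s_done <- 0; step <- 1; halvings <- 0L
  while (s_done < 1) {
    s_try <- min(1, s_done + step)
    res <- newton(set_dirichlet(uvec, s_try), s_try)
    if (res$ok) {
      uvec <- res$u; s_done <- s_try
      step <- min(2 * step, 1 - s_done + 1e-15)
    } else {
      halvings <- halvings + 1L
      if (halvings > max_halvings)
        numeric_error("forward solve failed to converge after %d load-step halvings (residual %g)",
                      max_halvings, final_res)
      step <- step / 2
    }
  }

  u <- matrix(uvec, n, 3L, byrow = TRUE)
  Fm <- batch_gradient(ops, u, add_identity = TRUE)
  J <- det3_batch(Fm)
  structure(list(u = u, converged = TRUE, residual = final_res,
                 iterations = total_iters, J_range = range(J),
                 mesh = mesh, params = params, b = b, fixed = fixed,
                 ops = ops),
            class = "forward_solution")
}

#' @export
print.forward_solution <- function(x, ...) {
  cat(sprintf("forward_solution: %s, %d Newton iterations, relative residual %.3g\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  cat(sprintf("  max |u| = %.4g m, J in [%.6f, %.6f]\n",
              max(sqrt(rowSums(x$u^2))), x$J_range[1], x$J_range[2]))
  invisible(x)
}
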