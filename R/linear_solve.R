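# Small-strain isotropic FE solver on linear tetrahedra.
#
# Used to generate the parameter-targeted virtual fields: all boundary
# (unknown-traction) nodes fixed, a small body load applied, and the
# linearized isotropic law with Lame parameters lambda = K - 2 mu / 3 and
# shear modulus mu.  Direct sparse Cholesky for determinism.

#' Assemble the global small-strain stiffness matrix
#'
#' @param mesh a [tet_mesh()].
#' @param mu shear modulus, Pa.
#' @param K bulk modulus, Pa.
#' @param ops precomputed [mesh_operators()].
#' @return sparse symmetric 3N x 3N stiffness (dof = 3*(node-1)+i).
#' @export
linear_stiffness <- function(mesh, mu, K, ops = mesh_operators(mesh)) {
  lam <- K - 2 * mu / 3
  G <- ops$G; V0 <- ops$V0
  x <- numeric(length(ops$asm_i))
  m <- ops$n_elements
  # K[(b,j),(a,i)] = V0 (lam G_bj G_ai + mu G_bi G_aj + mu d_ij G_a.G_b)
  dot_ab <- function(a, b)
    G[, (a - 1L) * 3L + 1L] * G[, (b - 1L) * 3L + 1L] +
    G[, (a - 1L) * 3L + 2L] * G[, (b - 1L) * 3L + 2L] +
    G[, (a - 1L) * 3L + 3L] * G[, (b - 1L) * 3L + 3L]
  for (a in 1:4) for (i in 1:3) {
    p <- (a - 1L) * 3L + i
    for (b in 1:4) {
      dab <- dot_ab(a, b)
      for (j in 1:3) {
        q <- (b - 1L) * 3L + j
        k <- (p - 1L) * 12L + q
        val <- lam * G[, (b - 1L) * 3L + j] * G[, (a - 1L) * 3L + i] +
               mu  * G[, (b - 1L) * 3L + i] * G[, (a - 1L) * 3L + j]
        if (i == j) val <- val + mu * dab
        x[((k - 1L) * m + 1L):(k * m)] <- V0 * val
      }
    }
  }
  Matrix::sparseMatrix(i = ops$asm_i, j = ops$asm_j, x = x,
                       dims = c(3L * ops$n_nodes, 3L * ops$n_nodes))
}

#' Consistent nodal body-force vector (rho V0 b / 4 to each vertex)
#' @noRd
body_force_vector <- function(mesh, b, ops) {
  w <- ops$V0 * mesh$density / 4
  f <- matrix(0, ops$n_nodes, 3L)
  W <- cbind(w, w, w, w)
  for (i in 1:3)
    f[, i] <- as.numeric(ops$scatter %*% as.vector(W)) * b[i]
  f
}

#' Solve the fixed-boundary small-strain elastic problem
#'
#' The virtual-field generator's workhorse: zero (or prescribed)
#' displacement on the fixed set, a body load elsewhere, isotropic moduli
#' (mu, K).  The strain-stiffening exponent has no linear-regime
#' footprint and does not enter.
#'
#' @param mesh a [tet_mesh()].
#' @param params an [ogden_params()] (only `mu`, `K` used).
#' @param body body force vector, m s^-2.
#' @param fixed node indices held fixed (default: all boundary nodes).
#' @param fixed_values optional matrix of prescribed displacements for the
#'   fixed nodes (length(fixed) x 3); zero if `NULL`.
#' @param ops optional precomputed [mesh_operators()].
#' @return N x 3 displacement field (metres), zero/prescribed on `fixed`.
#' @export
solve_fixed_boundary <- function(mesh, params, body,
                                 fixed = mesh$boundary_nodes,
                                 fixed_values = NULL,
                                 ops = mesh_operators(mesh)) {
  body <- as.numeric(body)
  if (length(body) != 3L) config_error("`body` must be a 3-vector")
  fixed <- sort(unique(as.integer(fixed)))
  if (!length(fixed)) config_error("fixed set is empty: rigid modes unconstrained")
  n <- ops$n_nodes
  u <- matrix(0, n, 3L)
  if (!is.null(fixed_values)) {
    fixed_values <- as.matrix(fixed_values)
    if (nrow(fixed_values) != length(fixed) || ncol(fixed_values) != 3L)
      config_error("`fixed_values` must be length(fixed) x 3")
    u[fixed, ] <- fixed_values
  }
  fixed_dofs <- as.vector(t(outer(3L * (fixed - 1L), 1:3, `+`)))
  free <- setdiff(seq_len(3L * n), fixed_dofs)
  if (!length(free)) return(u)  # fully constrained

  Kmat <- linear_stiffness(mesh, params$mu, params$K, ops)
  f <- as.vector(t(body_force_vector(mesh, body, ops)))
  rhs <- f[free] - as.numeric(Kmat[free, fixed_dofs, drop = FALSE] %*%
                                as.vector(t(u))[fixed_dofs])
  sol <- tryCatch(Matrix::solve(Kmat[free, free], rhs),
                  error = function(e)
                    numeric_error("singular linear system (insufficient constraints?): %s",
                                  conditionMessage(e)))
  uf <- as.vector(t(u)); uf[free] <- as.numeric(sol)
  matrix(uf, n, 3L, byrow = TRUE)
}
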