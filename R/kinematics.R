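# Large-deformation kinematics on linear (constant-strain) tetrahedra.
#
# For each element the reference shape-function gradients dN_a/dX are
# constant; with nodal displacements u_a the deformation gradient is
# F = I + sum_a u_a (dN_a/dX)^T, exact for affine fields.  Batch storage:
# gradients as an M x 12 matrix (columns (a-1)*3 + J), tensors as M x 9
# row-major packed rows.

#' Precompute per-element operators and assembly indices
#'
#' Computed once per mesh and reused by the power, solver and bundle code:
#' reference shape gradients, volumes, a sparse scatter matrix for nodal
#' force accumulation, and triplet indices for 12x12 stiffness assembly.
#'
#' @param mesh a [tet_mesh()].
#' @return an opaque list of class `mesh_operators`.
#' @export
mesh_operators <- function(mesh) {
  el <- mesh$elements
  m <- nrow(el); n <- nrow(mesh$nodes)
  a <- mesh$nodes[el[, 1L], , drop = FALSE]
  # edge matrix Dm columns X2-X1, X3-X1, X4-X1, packed row-major
  Dm <- matrix(0, m, 9L)
  for (b in 2:4) {
    e <- mesh$nodes[el[, b], , drop = FALSE] - a
    for (i in 1:3) Dm[, pack_idx(i, b - 1L)] <- e[, i]
  }
  detD <- det3_batch(Dm)
  Dinv <- inv3_batch(Dm, detD)   # rows r of Dinv are grad xi_r
  # G[, (a-1)*3 + J] = dN_a/dX_J ; N_{a+1} = xi_a, N_1 = 1 - sum xi
  G <- matrix(0, m, 12L)
  for (r in 1:3) for (J in 1:3)
    G[, r * 3L + J] <- Dinv[, pack_idx(r, J)]
  for (J in 1:3) G[, J] <- -(G[, 3L + J] + G[, 6L + J] + G[, 9L + J])

  scatter <- Matrix::sparseMatrix(i = as.vector(el), j = seq_len(4L * m),
                                  x = 1, dims = c(n, 4L * m))
  # triplet indices for 12x12 element-block assembly (dof = 3*(node-1)+i)
  dof <- function(nodes, i) 3L * (nodes - 1L) + i
  cols12 <- matrix(0L, m, 12L)
  for (a_ in 1:4) for (i in 1:3)
    cols12[, (a_ - 1L) * 3L + i] <- dof(el[, a_], i)
  ii <- matrix(0L, m, 144L); jj <- matrix(0L, m, 144L)
  for (p in 1:12) for (q in 1:12) {
    k <- (p - 1L) * 12L + q
    ii[, k] <- cols12[, q]   # row: test dof
    jj[, k] <- cols12[, p]   # col: trial dof
  }
  structure(list(G = G, V0 = mesh$volumes, elements = el,
                 n_nodes = n, n_elements = m,
                 scatter = scatter, asm_i = as.vector(ii), asm_j = as.vector(jj),
                 char_length = (6 * mean(mesh$volumes))^(1 / 3)),
            class = "mesh_operators")
}

#' Batch deformation (or displacement) gradients
#'
#' Returns the M x 9 packed gradients `dv/dX` of a nodal field `v`; with
#' `add_identity = TRUE` this is the deformation gradient F = I + du/dX.
#' @noRd
batch_gradient <- function(ops, v, add_identity = FALSE) {
  el <- ops$elements
  Fm <- matrix(0, ops$n_elements, 9L)
  for (i in 1:3) {
    va <- cbind(v[el[, 1L], i], v[el[, 2L], i], v[el[, 3L], i], v[el[, 4L], i])
    for (J in 1:3) {
      acc <- va[, 1] * ops$G[, J] + va[, 2] * ops$G[, 3L + J] +
             va[, 3] * ops$G[, 6L + J] + va[, 4] * ops$G[, 9L + J]
      Fm[, pack_idx(i, J)] <- if (add_identity && i == J) acc + 1 else acc
    }
  }
  Fm
}

#' Per-element large-deformation kinematics
#'
#' @param mesh a [tet_mesh()].
#' @param disp N x 3 nodal displacement matrix (metres).
#' @param element_index element number (1-based).
#' @param ops optional precomputed [mesh_operators()].
#' @return a list of class `element_kinematics` with fields `F` (3x3
#'   deformation gradient), `J` (det F), `V0` (reference volume, m^3) and
#'   `ref_shape_gradients` (3 x 4 matrix, column a = dN_a/dX).
#' @export
element_kinematics <- function(mesh, disp, element_index,
                               ops = mesh_operators(mesh)) {
  e <- as.integer(element_index)
  if (e < 1L || e > ops$n_elements) config_error("invalid element index %d", e)
  check_field(disp, mesh)
  Fm <- batch_gradient(ops, disp, add_identity = TRUE)[e, , drop = FALSE]
  J <- det3_batch(Fm)
  if (J <= 0)
    numeric_error("non-positive Jacobian (J = %g) in element %d", J, e)
  structure(list(F = unpack3(Fm[1, ]), J = as.numeric(J), V0 = ops$V0[e],
                 ref_shape_gradients = matrix(ops$G[e, ], 3L, 4L)),
            class = "element_kinematics")
}

#' Validate a nodal field against a mesh
#' @noRd
check_field <- function(u, mesh) {
  u <- as.matrix(u)
  if (nrow(u) != nrow(mesh$nodes) || ncol(u) != 3L)
    config_error("field must be %d x 3 (got %d x %d)",
                 nrow(mesh$nodes), nrow(u), ncol(u))
  if (any(!is.finite(u))) config_error("non-finite field components")
  u
}

#' Batch kinematics for a whole mesh: F, J, F^-1
#' @noRd
batch_kinematics <- function(ops, disp) {
  Fm <- batch_gradient(ops, disp, add_identity = TRUE)
  J <- det3_batch(Fm)
  if (any(J <= 0)) {
    bad <- which(J <= 0)
    numeric_error("non-positive Jacobian in element(s): %s",
                  paste(head(bad, 10L), collapse = ", "))
  }
  list(F = Fm, J = J, Finv = inv3_batch(Fm, J))
}
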