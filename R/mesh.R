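# Tetrahedral mesh container and generators.
#
# A `tet_mesh` holds reference node coordinates (metres), 4-node
# connectivity (1-based, positively oriented), the topological boundary
# node set (nodes on faces shared by exactly one element) and the tissue
# density.  Element orientation is fixed at construction by a single
# vertex-pair swap; a degenerate (zero-volume) element is an error.

#' Construct a tetrahedral mesh
#'
#' @param nodes numeric matrix, one node per row, columns x/y/z (metres,
#'   reference configuration).
#' @param elements integer matrix, one element per row, four 1-based node
#'   indices per row.
#' @param density tissue density in kg m^-3 (default 1040, a standard
#'   soft-tissue literature value).
#' @param fix_orientation if `TRUE` (default), elements with negative
#'   reference volume are repaired by swapping their last two vertices.
#' @return an object of class `tet_mesh` with fields `nodes`, `elements`,
#'   `density`, `volumes` (reference element volumes, m^3) and
#'   `boundary_nodes` (indices of nodes on the mesh surface).
#' @export
tet_mesh <- function(nodes, elements, density = 1040, fix_orientation = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3L) config_error("`nodes` must have 3 columns")
  if (any(!is.finite(nodes))) config_error("non-finite node coordinates")
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  dimnames(nodes) <- dimnames(elements) <- NULL
  if (ncol(elements) != 4L) config_error("`elements` must have 4 columns")
  n <- nrow(nodes)
  if (any(elements < 1L) || any(elements > n))
    config_error("connectivity refers to node indices outside 1..%d", n)
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    config_error("`density` must be a positive scalar (kg m^-3)")

  vol <- signed_tet_volumes(nodes, elements)
  if (fix_orientation && any(vol < 0)) {
    neg <- vol < 0
    elements[neg, c(3L, 4L)] <- elements[neg, c(4L, 3L)]
    vol <- signed_tet_volumes(nodes, elements)
  }
  if (any(vol <= 0)) {
    bad <- which(vol <= 0)
    numeric_error("degenerate or inverted element(s) that cannot be fixed by a vertex swap: %s",
                  paste(head(bad, 10L), collapse = ", "))
  }

  structure(list(nodes = nodes, elements = elements, density = density,
                 volumes = vol, boundary_nodes = boundary_node_set(elements)),
            class = "tet_mesh")
}

#' Signed reference volumes `det(cbind(X2-X1, X3-X1, X4-X1)) / 6`
#' @noRd
signed_tet_volumes <- function(nodes, elements) {
  a <- nodes[elements[, 1L], , drop = FALSE]
  e1 <- nodes[elements[, 2L], , drop = FALSE] - a
  e2 <- nodes[elements[, 3L], , drop = FALSE] - a
  e3 <- nodes[elements[, 4L], , drop = FALSE] - a
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
   e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
   e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
}

#' Nodes on faces shared by exactly one element
#' @noRd
boundary_node_set <- function(elements) {
  face_local <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
  faces <- do.call(rbind, lapply(1:4, function(f)
    elements[, face_local[f, ], drop = FALSE]))
  faces_sorted <- t(apply(faces, 1L, sort))
  key <- paste(faces_sorted[, 1], faces_sorted[, 2], faces_sorted[, 3])
  counts <- table(key)
  open <- names(counts)[counts == 1L]
  sort(unique(as.integer(unlist(strsplit(open, " ", fixed = TRUE)))))
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tet4 elements, %d boundary nodes\n",
              nrow(x$nodes), nrow(x$elements), length(x$boundary_nodes)))
  cat(sprintf("  total reference volume %.6g m^3, density %g kg m^-3\n",
              sum(x$volumes), x$density))
  invisible(x)
}

#' Structured cube mesh (Kuhn six-tetrahedra subdivision)
#'
#' Conforming tetrahedralisation of an axis-aligned cube: each of the
#' `n^3` grid cells is split into six tetrahedra along the main diagonal.
#'
#' @param n grid divisions per edge (default 6, the standard synthetic
#'   fixture size: 1296 elements).
#' @param edge cube edge length in metres (default 0.1).
#' @param density tissue density in kg m^-3.
#' @param origin coordinates of the minimum corner.
#' @return a [tet_mesh()].
#' @export
cube_mesh <- function(n = 6L, edge = 0.1, density = 1040, origin = c(0, 0, 0)) {
  n <- as.integer(n)
  if (n < 1L) config_error("`n` must be >= 1")
  g <- seq(0, edge, length.out = n + 1L)
  nodes <- as.matrix(expand.grid(x = g, y = g, z = g))
  nodes <- sweep(nodes, 2L, origin, `+`)
  dimnames(nodes) <- NULL
  idx <- function(i, j, k) i + (n + 1L) * (j - 1L) + (n + 1L)^2 * (k - 1L)

  cells <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  perms <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                 c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  ei <- diag(3L)
  elems <- vector("list", 6L)
  for (p in 1:6) {
    d1 <- ei[perms[p, 1L], ]; d12 <- d1 + ei[perms[p, 2L], ]
    v0 <- idx(cells$i, cells$j, cells$k)
    v1 <- idx(cells$i + d1[1], cells$j + d1[2], cells$k + d1[3])
    v2 <- idx(cells$i + d12[1], cells$j + d12[2], cells$k + d12[3])
    v3 <- idx(cells$i + 1L, cells$j + 1L, cells$k + 1L)
    elems[[p]] <- cbind(v0, v1, v2, v3)
  }
  tet_mesh(nodes, do.call(rbind, elems), density = density)
}

#' Thick ellipsoidal shell mesh (skull-confined organ surrogate)
#'
#' A cube-with-cubic-hole grid mapped radially onto a thick ellipsoidal
#' shell: the outer surface mimics the rigid confinement of a
#' skull-encased organ, the inner surface (a ventricle-like cavity) is
#' traction-free.  The returned mesh carries an `outer_nodes` attribute
#' giving the node set on the outer surface, to be used as the fixed set.
#'
#' @param n grid divisions per edge of the generating cube (even, >= 4).
#' @param semiaxes outer ellipsoid semi-axes in metres.
#' @param inner_fraction radial fraction of the inner cavity surface.
#' @param density tissue density in kg m^-3.
#' @return a [tet_mesh()] with attribute `outer_nodes`.
#' @export
shell_ellipsoid_mesh <- function(n = 8L, semiaxes = c(0.08, 0.07, 0.06),
                                 inner_fraction = 0.4, density = 1040) {
  n <- as.integer(n)
  if (n < 4L || n %% 2L != 0L) config_error("`n` must be an even integer >= 4")
  if (inner_fraction <= 0 || inner_fraction >= 1)
    config_error("`inner_fraction` must be in (0, 1)")
  # generating grid on [-1, 1]^3; drop cells inside the central hole
  g <- seq(-1, 1, length.out = n + 1L)
  h <- 2 / n
  nodes <- as.matrix(expand.grid(x = g, y = g, z = g))
  dimnames(nodes) <- NULL
  idx <- function(i, j, k) i + (n + 1L) * (j - 1L) + (n + 1L)^2 * (k - 1L)
  cells <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  centre <- cbind(g[cells$i] + h / 2, g[cells$j] + h / 2, g[cells$k] + h / 2)
  # hole = cells whose centre lies within the inner_fraction sup-norm box,
  # snapped to whole cells so the cavity surface is grid-aligned
  keep <- apply(abs(centre), 1L, max) > inner_fraction
  cells <- cells[keep, , drop = FALSE]

  perms <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                 c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  ei <- diag(3L)
  elems <- vector("list", 6L)
  for (p in 1:6) {
    d1 <- ei[perms[p, 1L], ]; d12 <- d1 + ei[perms[p, 2L], ]
    v0 <- idx(cells$i, cells$j, cells$k)
    v1 <- idx(cells$i + d1[1], cells$j + d1[2], cells$k + d1[3])
    v2 <- idx(cells$i + d12[1], cells$j + d12[2], cells$k + d12[3])
    v3 <- idx(cells$i + 1L, cells$j + 1L, cells$k + 1L)
    elems[[p]] <- cbind(v0, v1, v2, v3)
  }
  conn <- do.call(rbind, elems)
  used <- sort(unique(as.vector(conn)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  conn <- matrix(remap[conn], ncol = 4L)
  nodes <- nodes[used, , drop = FALSE]

  # radial map: sup-norm shells -> concentric ellipsoids
  supn <- apply(abs(nodes), 1L, max)
  eucl <- sqrt(rowSums(nodes^2))
  scale <- ifelse(eucl > 0, supn / eucl, 0)
  mapped <- nodes * scale
  mapped <- sweep(mapped, 2L, semiaxes, `*`)
  outer <- which(abs(supn - 1) < 1e-9)

  m <- tet_mesh(mapped, conn, density = density)
  attr(m, "outer_nodes") <- outer
  m
}
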