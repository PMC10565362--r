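# Shared fixtures (memoised: the expensive recovery bundles are built once
# per test run), independent finite-difference oracles, and in-code writers
# for the supported file dialects.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

true_params <- function() ogden_params(1250, -20, 254000)

# the standard synthetic fixture: 0.1 m cube, n = 6 (1296 tets), full
# gravity, forward-solved at the true parameters, fields on the same mesh
cube_recovery6 <- function() cached("rec6", function()
  make_recovery_bundle("cube", true_params(), n = 6))

cube_recovery4 <- function() cached("rec4", function()
  make_recovery_bundle("cube", true_params(), n = 4))

single_tet_mesh <- function(density = 1000) {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1), density = density)
}

# --- independent oracles -------------------------------------------------

# Cauchy stress by central finite differences of the strain energy through
# the deformation gradient: sigma = (dpsi/dF) F^T / J.
fd_cauchy_stress <- function(F, params, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (J in 1:3) {
    Fp <- F; Fp[i, J] <- Fp[i, J] + h
    Fm <- F; Fm[i, J] <- Fm[i, J] - h
    P[i, J] <- (strain_energy(Fp, params) - strain_energy(Fm, params)) / (2 * h)
  }
  P %*% t(F) / det(F)
}

# Deformation gradient of one element by central finite differences of the
# barycentric-interpolated map phi(X) = sum_a N_a(X) (X_a + u_a), probed at
# the element centroid.
fd_deformation_gradient <- function(mesh, disp, e, h = 1e-5) {
  verts <- mesh$nodes[mesh$elements[e, ], ]
  cur <- verts + disp[mesh$elements[e, ], ]
  M <- rbind(1, t(verts))            # barycentric system
  phi <- function(X) as.vector(t(cur) %*% solve(M, c(1, X)))
  X0 <- colMeans(verts)
  Fnum <- matrix(0, 3, 3)
  for (J in 1:3) {
    dX <- numeric(3); dX[J] <- h
    Fnum[, J] <- (phi(X0 + dX) - phi(X0 - dX)) / (2 * h)
  }
  Fnum
}

# Internal virtual power by a 4-point Gauss rule over each reference
# element (integrand evaluated independently at every quadrature point).
internal_power_4pt <- function(mesh, disp, vfield, params, ops) {
  a <- 0.5854101966249685; b <- 0.1381966011250105
  pts <- rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
  kin <- gravfm:::batch_kinematics(ops, disp)
  total <- 0
  for (e in seq_len(ops$n_elements)) {
    F <- matrix(kin$F[e, ], 3, 3, byrow = TRUE)
    G <- matrix(vfield$G[e, ], 3, 3, byrow = TRUE)
    D <- rate_of_deformation(G %*% solve(F))
    sig <- cauchy_stress(F, params)$sigma
    for (q in 1:4)  # constant-strain element: same integrand at each point
      total <- total + 0.25 * sum(sig * D) * det(F) * ops$V0[e]
  }
  total
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

random_F <- function(J_range = c(0.9, 1.1), stretch_range = c(0.8, 1.2)) {
  repeat {
    lam <- runif(3, stretch_range[1], stretch_range[2])
    Jt <- runif(1, J_range[1], J_range[2])
    lam <- lam * (Jt / prod(lam))^(1 / 3)
    F <- random_rotation() %*% diag(lam) %*% t(random_rotation())
    if (det(F) > 0) return(F)
  }
}

# --- file-dialect writers ------------------------------------------------

write_gmsh2_fixture <- function(path, swap = FALSE) {
  conn <- if (swap) "1 2 4 3" else "1 2 3 4"
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", "4",
               "1 0 0 0", "2 1 0 0", "3 0 1 0", "4 0 0 1",
               "$EndNodes",
               "$Elements", "2",
               "1 2 2 0 1 1 2 3",            # a surface triangle: ignored
               paste("2 4 2 0 1", conn),
               "$EndElements"), path)
  path
}

write_gmsh4_fixture <- function(path) {
  writeLines(c("$MeshFormat", "4.1 0 8", "$EndMeshFormat",
               "$Nodes", "1 4 1 4",
               "3 1 0 4", "1", "2", "3", "4",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "$EndNodes",
               "$Elements", "1 1 1 1",
               "3 1 4 1", "1 1 2 3 4",
               "$EndElements"), path)
  path
}

write_feb_fixture <- function(path) {
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<febio_spec version="4.0">',
               '  <Mesh>',
               '    <Nodes name="organ">',
               '      <node id="1">0,0,0</node>',
               '      <node id="2">1,0,0</node>',
               '      <node id="3">0,1,0</node>',
               '      <node id="4">0,0,1</node>',
               '    </Nodes>',
               '    <Elements type="tet4" name="part1">',
               '      <elem id="1">1,2,3,4</elem>',
               '    </Elements>',
               '  </Mesh>',
               '</febio_spec>'), path)
  path
}
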