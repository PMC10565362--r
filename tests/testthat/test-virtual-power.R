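# Virtual-power machinery: gradients, rates of deformation, powers,
# errors and the self-consistency check.

test_that("virtual velocity gradient closed forms", {
  G <- matrix(rnorm(9), 3)
  expect_equal(virtual_velocity_gradient(G, diag(3)), G)

  # diagonal case
  Gd <- diag(c(2, 3, 4))
  expect_equal(virtual_velocity_gradient(Gd, diag(c(2, 1, 1))),
               diag(c(1, 3, 4)))

  # v* = u on a random affine case reduces to (F - I) F^-1
  set.seed(31)
  A <- matrix(rnorm(9, sd = 0.1), 3)
  F <- diag(3) + A
  expect_equal(virtual_velocity_gradient(A, F), (F - diag(3)) %*% solve(F),
               tolerance = 1e-13)

  expect_error(virtual_velocity_gradient(G, matrix(0, 3, 3)), "singular")
})

test_that("rate of deformation is the symmetric part", {
  S <- matrix(rnorm(9), 3); S <- S + t(S)
  expect_equal(rate_of_deformation(S), S)
  W <- matrix(rnorm(9), 3); W <- W - t(W)
  expect_equal(rate_of_deformation(W), matrix(0, 3, 3))
  L <- matrix(0, 3, 3); L[1, 2] <- 1
  D <- rate_of_deformation(L)
  expect_equal(D, rbind(c(0, 0.5, 0), c(0.5, 0, 0), c(0, 0, 0)))
})

test_that("internal power vanishes for zero stress or rigid virtual fields", {
  m <- cube_mesh(2, edge = 0.1)
  ops <- mesh_operators(m)
  p <- true_params()
  u0 <- matrix(0, nrow(m$nodes), 3)
  v <- matrix(rnorm(3 * nrow(m$nodes), sd = 1e-3), ncol = 3)
  vf <- virtual_field(m, v, ops = ops, check = FALSE)
  expect_equal(internal_power(m, u0, vf, p, ops), 0)

  # constant virtual field: D* = 0 everywhere
  u <- homogeneous_fixture(diag(c(1.05, 1, 1)), n = 2)$disp
  v_const <- matrix(rep(c(1, 2, -1), each = nrow(m$nodes)), ncol = 3)
  vf_const <- virtual_field(m, v_const, ops = ops, check = FALSE)
  expect_equal(internal_power(m, u, vf_const, p, ops), 0, tolerance = 1e-12)
})

test_that("internal power matches the hand-evaluated homogeneous closed form", {
  # dilatation J on a cube, v* = beta X: sigma = K ln(J)/J I,
  # grad v* = beta J^(-1/3) I, P_int = 3 K ln(J) J^(-1/3) beta V_total
  p <- true_params()
  Jt <- 1.1; beta <- 2.5
  fix <- homogeneous_fixture(Jt^(1 / 3) * diag(3), n = 2, edge = 0.1)
  ops <- mesh_operators(fix$mesh)
  vf <- virtual_field(fix$mesh, fix$mesh$nodes * beta, ops = ops, check = FALSE)
  P_hand <- 3 * p$K * log(Jt) * Jt^(-1 / 3) * beta * 0.1^3
  expect_equal(internal_power(fix$mesh, fix$disp, vf, p, ops), P_hand,
               tolerance = 1e-9)
})

test_that("external power: hand value on a single tet, linearity, independence of disp", {
  m <- single_tet_mesh(density = 1000)
  ops <- mesh_operators(m)
  v <- matrix(0, 4, 3); v[, 3] <- 1e-3
  vf <- virtual_field(m, v, ops = ops, check = FALSE)
  b <- c(0, 0, -9.81)
  # rho V0 b . v = 1000 * (1/6) * (-9.81) * 1e-3
  expect_equal(external_power(m, vf, b, ops), -9.81e-3 * 1000 / 6,
               tolerance = 1e-12)
  expect_equal(external_power(m, vf, 2 * b, ops),
               2 * external_power(m, vf, b, ops))
  m2 <- single_tet_mesh(density = 2000)
  expect_equal(external_power(m2, vf, b, mesh_operators(m2)),
               2 * external_power(m, vf, b, ops))
  expect_equal(external_power(m, vf, c(0, 0, 0), ops), 0)
})

test_that("field and total error definitions", {
  expect_equal(field_error(1, 1), 0)
  expect_equal(field_error(1.05, 1), 0.05)
  expect_equal(field_error(0, 2), -1)
  expect_error(field_error(1, 0), "zero")
  expect_equal(total_error(c(0, 0, 0)), 0)
  expect_equal(total_error(c(0.3, 0.4, 0)), 0.5)
  expect_equal(total_error(c(-0.05, 0, 0)), 0.05)
  expect_gte(total_error(c(-0.2, 0.1, 0.05)), 0.2)
  expect_error(total_error(c(1, 2)), "length 3")
})

test_that("translation invariance and virtual-field scale invariance", {
  rec <- cube_recovery4()
  b0 <- rec$bundle
  p <- rec$params_true
  # adding a constant to the measured field changes no internal power
  shifted <- sweep(b0$disp, 2, c(0.01, -0.02, 0.005), `+`)
  b1 <- data_bundle(b0$mesh, shifted, b0$fields, b = b0$b, ops = b0$ops)
  expect_equal(evaluate_params(p, b1)$P_int, evaluate_params(p, b0)$P_int,
               tolerance = 1e-9)

  # scaling a virtual field scales both powers, leaving the error unchanged
  f2 <- lapply(b0$fields, function(vf) { vf$v <- vf$v * 1e3; vf$G <- vf$G * 1e3; vf })
  b2 <- data_bundle(b0$mesh, b0$disp, f2, b = b0$b, ops = b0$ops)
  e0 <- evaluate_params(p, b0); e2 <- evaluate_params(p, b2)
  expect_equal(e2$P_int, 1e3 * e0$P_int, tolerance = 1e-12)
  expect_equal(e2$P_ext, 1e3 * e0$P_ext, tolerance = 1e-12)
  expect_equal(e2$errors, e0$errors, tolerance = 1e-10)
})

test_that("one-point quadrature equals the 4-point rule on constant-strain elements", {
  set.seed(41)
  m <- cube_mesh(2, edge = 0.1)
  ops <- mesh_operators(m)
  p <- true_params()
  u <- matrix(rnorm(3 * nrow(m$nodes), sd = 5e-4), ncol = 3)
  v <- matrix(rnorm(3 * nrow(m$nodes), sd = 1e-3), ncol = 3)
  vf <- virtual_field(m, v, ops = ops, check = FALSE)
  expect_equal(internal_power(m, u, vf, p, ops),
               internal_power_4pt(m, u, vf, p, ops),
               tolerance = 1e-12)
})

test_that("self-consistency: tolerance monotonicity and the zero-load convention", {
  m <- cube_mesh(4)
  ops <- mesh_operators(m)
  p <- true_params()
  gaps <- sapply(c(1e-2, 1e-5, 1e-9), function(tol)
    self_consistency_check(forward_solve(m, p, tol = tol, ops = ops)))
  expect_lt(gaps[3], 1e-3)
  expect_true(all(diff(gaps) <= 0))     # gap grows with looser tolerance
  expect_gt(gaps[1], gaps[3])

  z <- forward_solve(m, p, b = c(0, 0, 0), ops = ops)
  expect_equal(z$u, matrix(0, nrow(m$nodes), 3))
  expect_equal(self_consistency_check(z), 0)

  bad <- forward_solve(m, p, ops = ops)
  bad$converged <- FALSE
  expect_error(self_consistency_check(bad), "converge")
})

test_that("virtual fields must vanish on the unknown-traction boundary", {
  m <- cube_mesh(2)
  v <- matrix(1, nrow(m$nodes), 3)
  expect_error(virtual_field(m, v), "non-zero")
  v[m$boundary_nodes, ] <- 0
  expect_silent(virtual_field(m, v))
})
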