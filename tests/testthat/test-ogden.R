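# One-term compressible Ogden law: closed forms, the finite-difference
# master oracle, objectivity, the isochoric/volumetric split, the alpha
# limit and the small-strain moduli conversions.

test_that("energy and stress vanish at the identity and match dilatation closed forms", {
  p <- true_params()
  expect_equal(strain_energy(diag(3), p), 0)
  expect_equal(cauchy_stress(diag(3), p)$sigma, matrix(0, 3, 3))

  # pure dilatation J = 1.1: deviatoric part zero, U(J) = (K/2)(ln J)^2,
  # sigma = K ln(J)/J I  (repeated-stretch case by construction)
  F <- 1.1^(1 / 3) * diag(3)
  expect_equal(strain_energy(F, p), p$K / 2 * log(1.1)^2, tolerance = 1e-12)
  s <- cauchy_stress(F, p)
  expect_equal(s$sigma, p$K * log(1.1) / 1.1 * diag(3), tolerance = 1e-10)
  expect_equal(s$principal_stretches_dev, rep(1, 3), tolerance = 1e-12)
})

test_that("simple shear matches the small-strain limit sigma_12 = mu * gamma", {
  p <- true_params()
  g <- 0.01
  F <- diag(3); F[1, 2] <- g
  s <- cauchy_stress(F, p)$sigma
  expect_equal(s[1, 2], p$mu * g, tolerance = 0.01)
  expect_equal(s[1, 2], s[2, 1])
})

test_that("stress matches central finite differences of the energy (master oracle)", {
  set.seed(101)
  for (rep in 1:100) {
    p <- ogden_params(10^runif(1, 2, 4), runif(1, -100, 100), 10^runif(1, 4, 6))
    F <- random_F()
    sig <- cauchy_stress(F, p)$sigma
    sig_fd <- fd_cauchy_stress(F, p)
    expect_lt(norm(sig - sig_fd, "F") / max(norm(sig, "F"), 1e-8), 1e-5)
  }
})

test_that("stress is objective and energy frame-indifferent", {
  set.seed(13)
  p <- true_params()
  for (rep in 1:10) {
    F <- random_F()
    R <- random_rotation()
    sR <- cauchy_stress(R %*% F, p)$sigma
    s <- cauchy_stress(F, p)$sigma
    expect_equal(sR, R %*% s %*% t(R), tolerance = 1e-10)
    expect_equal(strain_energy(R %*% F, p), strain_energy(F, p), tolerance = 1e-10)
  }
})

test_that("the deviatoric part is traceless and vanishing J-term leaves pure deviator", {
  set.seed(7)
  p <- true_params()
  for (rep in 1:10) {
    F <- random_F(J_range = c(1, 1))   # isochoric
    s <- cauchy_stress(F, p)$sigma
    # J = 1: sigma is purely deviatoric
    expect_lt(abs(sum(diag(s))) / max(norm(s, "F"), 1e-8), 1e-9)
  }
  # general F: volumetric part subtracts to a traceless deviator
  F <- random_F()
  s <- cauchy_stress(F, p)$sigma
  dev <- s - p$K * log(det(F)) / det(F) * diag(3)
  expect_lt(abs(sum(diag(dev))) / norm(s, "F"), 1e-10)
})

test_that("alpha crossing zero is continuous (analytic limit) and small strains are alpha-insensitive", {
  p0 <- true_params()
  set.seed(3)
  F <- random_F()
  near <- sapply(c(-1e-7, 1e-7), function(a) {
    p <- p0; p$alpha <- a
    c(strain_energy(F, p), cauchy_stress(F, p)$sigma[1, 2])
  })
  exact <- sapply(c(-1e-3, 1e-3), function(a) {
    p <- p0; p$alpha <- a
    c(strain_energy(F, p), cauchy_stress(F, p)$sigma[1, 2])
  })
  expect_equal(near[, 1], near[, 2], tolerance = 1e-6)
  expect_equal(rowMeans(near), rowMeans(exact), tolerance = 1e-4)

  # ||F - I|| <= 1e-3: stress changes < 0.5% as alpha spans [-100, 100]
  Fs <- diag(3) + matrix(rnorm(9, sd = 3e-4), 3)
  Fs <- Fs * (1 / det(Fs))^(1 / 3) * 1.0002
  sigs <- lapply(c(-100, -50, 0, 50, 100), function(a) {
    p <- p0; p$alpha <- a
    cauchy_stress(Fs, p)$sigma
  })
  ref <- sigs[[3]]
  for (s in sigs)
    expect_lt(norm(s - ref, "F") / norm(ref, "F"), 0.005)
})

test_that("small-strain slopes recover mu (shear) and K (hydrostatic)", {
  p <- true_params()
  g <- 1e-6
  F <- diag(3); F[1, 2] <- g
  expect_equal(cauchy_stress(F, p)$sigma[1, 2] / g, p$mu, tolerance = 1e-4)
  dJ <- 1e-6
  Fv <- (1 + dJ)^(1 / 3) * diag(3)
  pr <- sum(diag(cauchy_stress(Fv, p)$sigma)) / 3
  expect_equal(pr / log(1 + dJ), p$K, tolerance = 1e-4)
})

test_that("small-strain moduli conversions are standard and bounded", {
  # headline conversion: mu = 1.25 kPa, K = 254 kPa -> E rounds to 3744 Pa
  mods <- small_strain_moduli(ogden_params(1250, -20, 254000))
  expect_equal(round(mods[["E"]]), 3744)
  expect_equal(mods[["nu"]], (3 * 254000 - 2 * 1250) / (6 * 254000 + 2 * 1250))

  # near-incompressible regime: nu -> 0.4995, always < 0.5
  mods2 <- small_strain_moduli(ogden_params(100, -20, 1e5))
  expect_equal(mods2[["nu"]], 0.4995, tolerance = 1e-3)
  expect_lt(mods2[["nu"]], 0.5)

  # closed-form zero: 2 mu = 3 K -> nu = 0 exactly
  expect_equal(small_strain_moduli(ogden_params(1500, -20, 1000))[["nu"]], 0)

  expect_error(small_strain_moduli(list(mu = -1, K = 1)), "mu and K")
})

test_that("non-positive Jacobians are rejected", {
  p <- true_params()
  F <- diag(c(1, 1, -1))
  expect_error(strain_energy(F, p), "Jacobian")
  expect_error(cauchy_stress(F, p), "Jacobian")
})
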