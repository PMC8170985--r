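test_that("penalty exponent follows both conventions and rejects nu >= 0.5", {
  expect_identical(penalty_exponent(0), 0)
  expect_identical(penalty_exponent(0, "paper"), 0)
  expect_equal(penalty_exponent(0.3, "paper"), -0.75)
  expect_equal(penalty_exponent(0.3, "standard"), 0.75)
  expect_error(penalty_exponent(0.5), class = "foamfem_invalid_argument")
  expect_error(penalty_exponent(-0.1), class = "foamfem_invalid_argument")
})

test_that("strain energy matches hand-evaluated cases and is symmetric in the stretches", {
  mat <- test_material()
  expect_equal(hill_energy(c(1, 1, 1), mat), 0)

  # single term C = 1 kPa, b = 2, isochoric stretch: bracket = 2, Psi = 1 kPa
  m1 <- material_constants(1000, 1e6, 1e4, 0.3, C = 1e3, b = 2)
  lam <- c(2, 2^-0.5, 2^-0.5)
  expect_equal(hill_energy(lam, m1), 1e3, tolerance = 1e-12)
  # penalty term contributes nothing for J = 1, any convention
  m1p <- material_constants(1000, 1e6, 1e4, 0.3, C = 1e3, b = 2,
                            convention = "paper")
  expect_equal(hill_energy(lam, m1p), 1e3, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:100) {
    l <- stats::runif(3, 0.5, 2)
    expect_equal(hill_energy(l, mat), hill_energy(l[c(2, 1, 3)], mat))
    expect_equal(hill_energy(l, mat), hill_energy(l[c(3, 2, 1)], mat))
  }
})

test_that("principal stresses match the closed form and the energy gradient", {
  m1 <- material_constants(1000, 1e6, 1e4, 0.3, C = 1e3, b = 2)
  expect_equal(principal_stresses(c(1, 1, 1), m1), c(0, 0, 0))
  expect_equal(principal_stresses(c(2, 2^-0.5, 2^-0.5), m1),
               c(3e3, -0.5e3, -0.5e3), tolerance = 1e-12)

  mat <- test_material()
  set.seed(21)
  for (i in 1:100) {
    lam <- stats::runif(3, 0.6, 1.8)
    expect_equal(principal_stresses(lam, mat),
                 numeric_principal_stresses(lam, mat),
                 tolerance = 1e-6)
  }
  # n = 0 analytic limit also agrees with its numerical gradient
  m0 <- material_constants(1000, 1e6, 1e4, 0, C = c(1e3, 5e2), b = c(2, -1))
  lam <- c(1.4, 0.8, 1.1)
  expect_equal(principal_stresses(lam, m0),
               numeric_principal_stresses(lam, m0), tolerance = 1e-6)
})

test_that("spectral stress assembly round-trips and validates its triad", {
  expect_equal(assemble_cauchy_stress(c(5, 5, 5), diag(3)), diag(5, 3))
  Q <- random_rotation()
  expect_equal(assemble_cauchy_stress(c(2, 2, 2), Q), diag(2, 3))
  S <- assemble_cauchy_stress(c(1, 0, 0), diag(3))
  expect_equal(S, diag(c(1, 0, 0)))

  set.seed(31)
  for (i in 1:20) {
    sig <- stats::rnorm(3)
    Q <- random_rotation()
    T <- assemble_cauchy_stress(sig, Q)
    expect_equal(T, t(T))
    ev <- eigen(T, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sort(ev), sort(sig), tolerance = 1e-10)
  }
  expect_error(assemble_cauchy_stress(1:3, diag(3) * 1.01),
               class = "foamfem_invalid_triad")
})

test_that("objectivity: rotating F rotates the assembled Cauchy stress", {
  mat <- test_material()
  set.seed(41)
  for (i in 1:25) {
    F <- random_F()
    Q <- random_rotation()
    S <- cauchy_stress(F, mat)
    SQ <- cauchy_stress(Q %*% F, mat)
    expect_equal(SQ, Q %*% S %*% t(Q), tolerance = 1e-9)
  }
})

test_that("uniaxial stress: closed form, numerical equilibrium and lateral law agree", {
  expect_equal(uniaxial_nominal_stress(1, test_material()), 0)

  m <- material_constants(1000, 1e6, 1e4, 0.3, C = 1e4, b = 4)
  expect_equal(uniaxial_nominal_stress(1.5, m),
               1e4 * (1.5^3 - 1.5^-2.2), tolerance = 1e-12)
  expect_equal(uniaxial_nominal_stress(1.5, m, method = "root"),
               1e4 * (1.5^3 - 1.5^-2.2), tolerance = 1e-9)
  # lateral solution is independent of the exponent set
  expect_equal(lateral_stretch(2, m), 2^-0.3, tolerance = 1e-12)
  m2 <- material_constants(1000, 1e6, 1e4, 0.3, C = c(1e4, 2e3), b = c(4, -2))
  expect_equal(lateral_stretch(2, m2, method = "root"), 2^-0.3,
               tolerance = 1e-9)

  set.seed(51)
  for (i in 1:20) {
    nu <- stats::runif(1, 0.05, 0.45)
    lam <- stats::runif(1, 0.7, 1.8)
    bset <- sample(c(1, 2, 4, -1, -2), 3)
    mi <- material_constants(1000, 1e6, 1e4, nu,
                             C = stats::runif(3, 1e3, 1e4), b = bset)
    expect_equal(lateral_stretch(lam, mi, method = "root"), lam^-nu,
                 tolerance = 1e-6)
  }
})

test_that("curve fitting recovers known constants and is linear in SFO", {
  m <- material_constants(1000, 1e6, 1e4, 0.3, C = 1e4, b = 4)
  eps <- seq(0.02, 0.5, length.out = 20)
  curve <- load_curve(eps, uniaxial_nominal_stress(1 + eps, m))
  fit <- fit_constants_to_curve(curve, 0.3, exponents = 4)
  expect_equal(fit$C, 1e4, tolerance = 1e-6)
  expect_lt(fit$rms_frac, 1e-9)

  curve2 <- load_curve(eps, uniaxial_nominal_stress(1 + eps, m), sfo = 2)
  fit2 <- fit_constants_to_curve(curve2, 0.3, exponents = 4)
  expect_identical(fit2$C, 2 * fit$C)

  # multi-exponent basis also recovers the generating term
  fitm <- fit_constants_to_curve(curve, 0.3, exponents = c(1, 2, 4, -1, -2))
  expect_equal(fitm$C[3], 1e4, tolerance = 1e-4)

  expect_error(fit_constants_to_curve(curve, 0.3, exponents = c(2, 2)),
               class = "foamfem_rank_deficient")
})

test_that("small-strain linear curve yields a material with matching tangent", {
  E <- 4e4
  eps <- seq(0, 0.02, length.out = 21)
  curve <- load_curve(eps, E * eps)
  mat <- curve_material(curve, density = 1000, K = 1e6, G = 1.6e4, nu = 0.3)
  expect_equal(tangent_young_modulus(mat), E,
               tolerance = 10 * mat$fit$rms / E + 1e-3)
})

test_that("curve-driven stresses scale exactly with SFO at fixed deformation", {
  base <- default_soft_tissue_curve()
  m1 <- curve_material(base, density = 1000, K = 1e6, G = 1.6e4, nu = 0.3)
  set.seed(61)
  for (sfo in c(0.5, 2, 10)) {
    ms <- curve_material(load_curve(base$strain, base$stress, sfo = sfo),
                         density = 1000, K = 1e6, G = 1.6e4, nu = 0.3)
    for (i in 1:10) {
      F <- random_F()
      expect_equal(cauchy_stress(F, ms), sfo * cauchy_stress(F, m1),
                   tolerance = 1e-10)
    }
  }
})

test_that("rate tables select, interpolate in log-rate, and clamp", {
  y <- c(0, 1e3, 3e3)
  eps <- c(0, 0.1, 0.3)
  tab <- rate_table(c(1, 9), list(load_curve(eps, y), load_curve(eps, 3 * y)))
  expect_identical(curve_stress(select_rate_curve(tab, 1)), y)
  expect_identical(curve_stress(select_rate_curve(tab, 9)), 3 * y)
  # geometric-mean rate -> arithmetic-mean ordinates: 2y
  expect_equal(curve_stress(select_rate_curve(tab, 3)), 2 * y)
  expect_identical(curve_stress(select_rate_curve(tab, 0.1)), y)
  expect_identical(curve_stress(select_rate_curve(tab, 100)), 3 * y)
  expect_error(rate_table(c(2, 1), list()), class = "foamfem_invalid_table")
})

test_that("load curves anchor the origin and validate their inputs", {
  lc <- load_curve(c(0.1, 0.2), c(1, 2), sfo = 2)
  expect_identical(curve_strain(lc)[1], 0)
  expect_identical(curve_stress(lc), c(0, 2, 4))
  expect_error(load_curve(c(0.2, 0.1), c(1, 2)), class = "foamfem_invalid_curve")
  expect_error(load_curve(0, 1), class = "foamfem_invalid_curve")
  expect_error(material_constants(1000, 1e6, 1e4, 0.3, C = 1, b = 0),
               class = "foamfem_invalid_material")
})
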