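test_that("effective stress matches the sqrt(3 J2) invariant oracle", {
  expect_equal(effective_stress(c(5, 5, 5)), 0)
  expect_equal(effective_stress(c(1, 0, 0)), 1)
  expect_equal(effective_stress(c(3, -0.5, -0.5)), 3.5)

  set.seed(101)
  for (i in 1:1000) {
    S <- random_sym(scale = 10)
    dev <- S - diag(mean(diag(S)), 3)
    J2 <- 0.5 * sum(dev * dev)
    expect_equal(effective_stress(S), sqrt(3 * J2), tolerance = 1e-10)
  }
})

test_that("effective measures are rotation invariant", {
  set.seed(111)
  for (i in 1:50) {
    S <- random_sym()
    Q <- random_rotation()
    SR <- Q %*% S %*% t(Q)
    expect_equal(effective_stress(SR), effective_stress(S), tolerance = 1e-10)
    expect_equal(effective_strain(SR), effective_strain(S), tolerance = 1e-10)
  }
})

test_that("effective strain contraction on canonical states", {
  expect_equal(effective_strain(matrix(0, 3, 3)), 0)
  e <- 0.37
  expect_equal(effective_strain(diag(c(e, -e / 2, -e / 2))), e)
  g <- 0.2   # pure shear eps_12 = gamma/2
  S <- matrix(0, 3, 3); S[1, 2] <- S[2, 1] <- g / 2
  expect_equal(effective_strain(S), g / sqrt(3))
  # Voigt input equivalence
  expect_equal(effective_strain(c(e, -e / 2, -e / 2, 0, 0, 0)), e)
})

test_that("effective plastic strain accumulates and is resampling invariant", {
  tm <- seq(0, 1, length.out = 11)
  elastic <- element_history(1, tm, matrix(0, 11, 6), matrix(0, 11, 6))
  expect_message(eps <- effective_plastic_strain(elastic), "no plastic")
  expect_identical(eps, numeric(11))

  d <- 2e-3
  inc <- matrix(rep(c(d, -d / 2, -d / 2, 0, 0, 0), each = 11), 11, 6)
  inc[1, ] <- 0
  h <- element_history(1, tm, matrix(0, 11, 6), matrix(0, 11, 6),
                       plastic_increment = inc)
  series <- effective_plastic_strain(h)
  expect_equal(series[11], 10 * d, tolerance = 1e-12)
  expect_true(all(diff(series) >= 0))

  # splitting each increment into halves over twice the samples is invariant
  tm2 <- seq(0, 1, length.out = 21)
  inc2 <- matrix(rep(c(d, -d / 2, -d / 2, 0, 0, 0) / 2, each = 21), 21, 6)
  inc2[1, ] <- 0
  h2 <- element_history(1, tm2, matrix(0, 21, 6), matrix(0, 21, 6),
                        plastic_increment = inc2)
  expect_equal(effective_plastic_strain(h2)[21], series[11], tolerance = 1e-12)

  set.seed(121)
  rnd <- matrix(abs(stats::rnorm(11 * 6, sd = 1e-3)), 11, 6)
  hr <- element_history(1, tm, matrix(0, 11, 6), matrix(0, 11, 6),
                        plastic_increment = rnd)
  expect_true(all(diff(effective_plastic_strain(hr)) >= 0))
})

test_that("Young's modulus fit recovers slopes and scales with stress", {
  eps <- seq(0, 0.3, length.out = 40)
  sig <- 4e4 * eps
  fit <- fit_young_modulus(sig, eps)
  expect_equal(fit$modulus, 4e4, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)

  set.seed(131)
  noisy <- sig + stats::rnorm(40, sd = 100)
  fn <- fit_young_modulus(noisy, eps)
  se <- 100 / (stats::sd(eps) * sqrt(39))     # approximate slope s.e.
  expect_lt(abs(fn$modulus - 4e4), 3 * se)

  f2 <- fit_young_modulus(2 * noisy, eps)
  expect_equal(f2$modulus, 2 * fn$modulus, tolerance = 1e-12)

  # auto window: contiguous run with stress >= 25% of peak
  hump <- sin(pi * seq(0, 1, length.out = 50))
  fh <- fit_young_modulus(hump, seq(0, 1, length.out = 50))
  expect_true(all(hump[fh$window[1]:fh$window[2]] >= 0.25 * max(hump) - 1e-12))
  expect_error(fit_young_modulus(c(1, 2, 3), c(1, 1, 1)),
               class = "foamfem_degenerate_window")
})

test_that("log strain: canonical values and trace identity", {
  expect_equal(log_strain(diag(3)), matrix(0, 3, 3))
  expect_equal(log_strain(diag(c(1.5, 1, 1))), diag(c(log(1.5), 0, 0)))
  set.seed(141)
  for (i in 1:30) {
    F <- random_F()
    expect_equal(sum(diag(log_strain(F))), log(det(F)), tolerance = 1e-9)
  }
})
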