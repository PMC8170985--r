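mk_hist <- function(id, peak, volume, label = "muscle", side = "center",
                    n = 20L) {
  tm <- seq(0, 0.05, length.out = n)
  e_ax <- peak * sin(pi * seq(0, 1, length.out = n))^2
  strain <- cbind(e_ax, -e_ax / 2, -e_ax / 2, 0, 0, 0)
  element_history(id, tm, stress = strain * 4e4, strain = strain,
                  volume = volume, part = id, label = label, side = side)
}

test_that("failed element volume enumerates exactly and is monotone in threshold", {
  hs <- list(mk_hist(1, 0.01, 1e-9), mk_hist(2, 0.05, 2e-9),
             mk_hist(3, 0.08, 3e-9))

  quiet <- failed_element_volume(hs, "effective_strain", threshold = 0.5)
  expect_identical(quiet$volume, numeric(20))

  fv <- failed_element_volume(hs, "effective_strain", threshold = 0.02)
  expect_equal(fv$volume[length(fv$volume)], 5e-9, tolerance = 1e-12)
  expect_true(all(diff(fv$volume) >= 0))
  expect_setequal(fv$parts, c(2, 3))

  for (thr in c(0.005, 0.02, 0.06, 0.2)) {
    lo <- failed_element_volume(hs, "effective_strain", threshold = thr)
    hi <- failed_element_volume(hs, "effective_strain", threshold = thr * 1.5)
    expect_true(all(hi$volume <= lo$volume + 1e-15))
  }

  # strict exceedance: an element exactly at the threshold never fails
  flat <- mk_hist(9, 0.02, 1e-9)
  flat$strain[] <- 0.02
  flat$strain[, 2:6] <- 0
  ex <- failed_element_volume(list(flat), "effective_strain",
                              threshold = effective_strain(c(0.02, 0, 0, 0, 0, 0)))
  expect_identical(ex$volume, numeric(20))

  expect_error(failed_element_volume(hs, "nonsense"))
})

test_that("instantaneous mode drops elements that recover", {
  h <- mk_hist(1, 0.5, 1e-9)
  acc <- failed_element_volume(list(h), "effective_strain", 0.2)
  ins <- failed_element_volume(list(h), "effective_strain", 0.2,
                               accumulate = FALSE)
  expect_equal(acc$volume[length(acc$volume)], 1e-9)
  expect_equal(ins$volume[length(ins$volume)], 0)    # strain decays again
  expect_true(all(ins$volume <= acc$volume))
})

test_that("csdm groups by tissue and side with once-failed accumulation", {
  hs <- list(mk_hist(1, 0.8, 1e-9, "muscle", "left"),
             mk_hist(2, 0.3, 2e-9, "muscle", "left"),
             mk_hist(3, 0.9, 4e-9, "soft", "right"))
  cs <- csdm(hs)
  expect_equal(cs$threshold, 0.59)
  gl <- cs$groups[["muscle/left"]]
  expect_equal(gl$volume[length(gl$volume)], 1e-9)
  expect_equal(gl$fraction[length(gl$fraction)], 1e-9 / 3e-9)
  gr <- cs$groups[["soft/right"]]
  expect_equal(gr$fraction[length(gr$fraction)], 1)
  expect_true(all(vapply(cs$groups, function(g) all(g$fraction >= 0 & g$fraction <= 1),
                         logical(1))))

  none <- csdm(list(mk_hist(1, 0.2, 1e-9)))
  expect_identical(none$groups[[1]]$volume, numeric(20))

  one <- mk_hist(1, 1.0, 1e-9)
  c1 <- csdm(list(one))
  first_over <- which(apply(one$strain, 1, effective_strain) > 0.59)[1]
  expect_identical(which(c1$groups[[1]]$volume > 0)[1], first_over)
})

test_that("csdm threshold derives from failure statistics", {
  expect_equal(csdm_threshold_from_failure_stats(95, 36), 59)
  expect_equal(csdm_threshold_from_failure_stats(0.95, 0.36), 0.59)
  expect_equal(csdm_threshold_from_failure_stats(0.4, 0), 0.4)
  expect_equal(csdm_threshold_from_failure_stats(100, 25), 75)
  expect_error(csdm_threshold_from_failure_stats(30, 36),
               class = "foamfem_invalid_argument")
})

test_that("first principal strain: spectral value and Rayleigh oracle", {
  expect_equal(first_principal_strain(diag(c(0.02, -0.01, 0))), 0.02)
  Q <- random_rotation()
  expect_equal(first_principal_strain(Q %*% diag(c(0.02, -0.01, 0)) %*% t(Q)),
               0.02, tolerance = 1e-12)

  set.seed(151)
  S <- random_sym()
  dirs <- matrix(stats::rnorm(3e4), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  brute <- max(rowSums((dirs %*% S) * dirs))
  expect_equal(first_principal_strain(S), brute, tolerance = 1e-3)
})

test_that("peak force takes the first maximum; risk lookup interpolates and clamps", {
  ramp <- peak_force(c(0, 1, 2, 3), time = c(0, 1, 2, 3))
  expect_equal(ramp$value, 3); expect_equal(ramp$time, 3)
  tie <- peak_force(c(0, 5, 2, 5, 1), time = 1:5)
  expect_equal(tie$time, 2)
  zero <- peak_force(c(0, 0, 0), time = c(0.1, 0.2, 0.3))
  expect_equal(zero$value, 0); expect_equal(zero$time, 0.1)

  rc <- risk_curve(c(1e3, 3e3), c(0.2, 0.6), label = "hip AIS2+")
  expect_equal(risk_lookup(rc, 1e3), 0.2)
  expect_equal(risk_lookup(rc, 2e3), 0.4)
  expect_equal(risk_lookup(rc, 10), 0.2)
  expect_equal(risk_lookup(rc, 1e6), 0.6)
  set.seed(161)
  f <- sort(stats::runif(50, 0, 5e3))
  expect_true(all(diff(risk_lookup(rc, f)) >= 0))
  expect_error(risk_curve(c(2, 1), c(0.1, 0.2)),
               class = "foamfem_invalid_risk_curve")
  expect_error(risk_curve(c(1, 2), c(0.5, 0.2)),
               class = "foamfem_invalid_risk_curve")
})

test_that("injury report bundles criteria, peak force and risk", {
  hs <- list(mk_hist(1, 0.8, 1e-9), mk_hist(2, 0.1, 2e-9))
  contact <- data.frame(time = c(0, 1, 2), magnitude = c(0, 2e3, 1e3))
  rc <- risk_curve(c(1e3, 3e3), c(0.2, 0.6), label = "hip AIS2+")
  rep <- injury_report(hs, contact = contact, risk_curves = list(rc))
  expect_equal(rep$peak_force$value, 2e3)
  expect_equal(unname(rep$risk["hip AIS2+"]), 0.4)
  expect_named(rep$failed, c("effective_plastic_strain", "first_principal_strain"))
  expect_true(all(rep$csdm$groups[[1]]$fraction <= 1))
})
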