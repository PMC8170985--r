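# Shared test utilities: random deformation states, a default test
# material, and a cache so expensive simulation runs are shared between
# test files (testthat keeps helpers loaded for the whole run).

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# random deformation gradient with J > 0, bounded away from extremes
random_F <- function() {
  repeat {
    F <- diag(3) + matrix(stats::runif(9, -0.3, 0.3), 3, 3)
    if (det(F) > 0.3) return(F)
  }
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

random_sym <- function(scale = 1) {
  A <- matrix(stats::rnorm(9, sd = scale), 3, 3)
  (A + t(A)) / 2
}

test_material <- function(C = c(5e3, 2e3), b = c(2, 4), nu = 0.3,
                          convention = "standard") {
  material_constants(density = 1000, K = 1e6, G = 1.6e4, nu = nu,
                     C = C, b = b, convention = convention)
}

# central-difference numerical gradient of the strain energy wrt stretches
numeric_principal_stresses <- function(lam, mat, h = 1e-6) {
  J <- prod(lam)
  vapply(1:3, function(a) {
    lp <- lam; lm <- lam
    lp[a] <- lam[a] + h; lm[a] <- lam[a] - h
    dPsi <- (hill_energy(lp, mat) - hill_energy(lm, mat)) / (2 * h)
    lam[a] * dPsi / J
  }, numeric(1))
}

drop_run <- function(sfo) {
  cached(paste0("drop_sfo_", sfo), run_simulation(make_drop_block(sfo = sfo)))
}

coupon_run <- function(sfo) {
  cached(paste0("coupon_sfo_", sfo), run_simulation(make_uniaxial_coupon(sfo = sfo)))
}

cuboid_run <- function(key, ...) {
  cached(paste0("cuboid_", key), run_simulation(make_cuboid8(...)))
}
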