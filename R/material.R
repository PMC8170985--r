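#' Penalty exponent of the foam volumetric term
#'
#' The compressible Ogden-type foam energy penalizes volume change through a
#' term `(1/n)(J^(-n b_j) - 1)` per Ogden term; the exponent `n` is tied to
#' the Poisson ratio. Two conventions are supported: `"standard"` (default),
#' `n = nu / (1 - 2 nu)`, which yields the physically expected uniaxial
#' lateral contraction `lambda_lat = lambda_axial^(-nu)`; and `"paper"`,
#' `n = nu / (2 nu - 1)`, the sign variant that appears in some material
#' documentation and gives lateral expansion under tension for small `nu`.
#'
#' @param nu Poisson ratio, `0 <= nu < 0.5`.
#' @param convention `"standard"` or `"paper"`.
#' @return The penalty exponent `n` (dimensionless). `nu = 0` gives `n = 0`
#'   under both conventions; callers must then use the analytic limit
#'   `-b_j log(J)` of the penalty term.
#' @export
penalty_exponent <- function(nu, convention = c("standard", "paper")) {
  convention <- match.arg(convention)
  stopifnot_scalar(nu, "nu")
  if (nu < 0 || nu >= 0.5) {
    ff_stop("foamfem_invalid_argument",
            "nu must be in [0, 0.5): the incompressible limit is unsupported (got %g)", nu)
  }
  if (nu == 0) return(0)
  switch(convention,
         standard = nu / (1 - 2 * nu),
         paper    = nu / (2 * nu - 1))
}

#' Material constants of the hyperelastic simplified-foam model
#'
#' Bundles the keyword-card fields (density RHO, linear bulk modulus KM,
#' shear modulus G, damping coefficient MU, limit stress SIGF) with the
#' Ogden-term set `(C_j, b_j)`, the Poisson ratio and the derived penalty
#' exponent. Following the reference solver's documented behavior, `KM` is
#' used only for the CFL time step and contact stiffness, and `MU`/`SIGF`
#' are parsed and stored but have no constitutive effect.
#'
#' @param density Mass density (kg/m^3), > 0.
#' @param K Linear bulk modulus KM (Pa), > 0. Time-step/contact use only.
#' @param G Shear modulus (Pa), > 0. Time-step use only.
#' @param nu Poisson ratio in [0, 0.5).
#' @param C Ogden coefficients C_j (Pa), length m >= 1.
#' @param b Ogden exponents b_j (dimensionless, finite, nonzero), length m.
#' @param mu Damping coefficient MU (dimensionless, stored only).
#' @param sigf Limit stress SIGF (Pa, stored only).
#' @param convention Penalty-exponent convention, see [penalty_exponent()].
#' @param id Optional material id (integer) for deck round-tripping.
#' @return An object of class `foam_material`.
#' @seealso [curve_material()] to derive the Ogden terms from a load curve.
#' @export
material_constants <- function(density, K, G, nu, C, b,
                               mu = 0, sigf = 0,
                               convention = c("standard", "paper"),
                               id = 1L) {
  convention <- match.arg(convention)
  stopifnot_scalar(density, "density", positive = TRUE)
  stopifnot_scalar(K, "K", positive = TRUE)
  stopifnot_scalar(G, "G", positive = TRUE)
  C <- as.numeric(C); b <- as.numeric(b)
  if (length(C) < 1L || length(C) != length(b)) {
    ff_stop("foamfem_invalid_material", "C and b must be equal-length, m >= 1")
  }
  if (any(!is.finite(b)) || any(b == 0) || any(!is.finite(C))) {
    ff_stop("foamfem_invalid_material", "all b_j must be finite and nonzero, C_j finite")
  }
  n <- penalty_exponent(nu, convention)
  structure(list(
    id = as.integer(id), density = density, K = K, G = G,
    mu = mu, sigf = sigf, nu = nu, n = n, convention = convention,
    C = C, b = b, m = length(C),
    curve = NULL, fit = NULL, rate_fit = NULL
  ), class = "foam_material")
}

#' @export
print.foam_material <- function(x, ...) {
  cat(sprintf("<foam_material %d> rho=%g kg/m^3, KM=%g Pa, G=%g Pa, nu=%g (n=%g, %s)\n",
              x$id, x$density, x$K, x$G, x$nu, x$n, x$convention))
  cat("  terms: ", paste(sprintf("C=%.6g b=%g", x$C, x$b), collapse = "; "), "\n")
  if (!is.null(x$fit)) {
    cat(sprintf("  fitted from curve (SFO=%g), RMS residual %.3g Pa\n",
                x$curve$sfo, x$fit$rms))
  }
  if (!is.null(x$rate_fit)) {
    cat(sprintf("  strain-rate table: %d rates in [%g, %g] 1/s\n",
                length(x$rate_fit$rates), min(x$rate_fit$rates), max(x$rate_fit$rates)))
  }
  invisible(x)
}

# Per-term evaluation of the penalty bracket (1/n)(J^(-n b) - 1) with the
# analytic n -> 0 limit -b log(J).
penalty_bracket <- function(J, n, b) {
  if (n == 0) -b * log(J) else (J^(-n * b) - 1) / n
}

#' Deformation state from a deformation gradient
#'
#' Spectral kinematics for the principal-stretch material: right
#' Cauchy-Green tensor `C = t(F) %*% F`, principal stretches, material
#' eigenvectors `N_a` and the spatial principal triad `n_a = F N_a /
#' lambda_a` (the left-stretch eigenvectors, which keep the assembled
#' Cauchy stress objective), plus the Jacobian `J = det(F)`.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @return An object of class `deformation_state` with fields `F`, `C`,
#'   `lambda` (decreasing), `N`, `n` (columns are eigenvectors), `J`.
#' @export
deformation_state <- function(F) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3L, 3L)) || any(!is.finite(F))) {
    ff_stop("foamfem_invalid_deformation", "F must be a finite 3x3 matrix")
  }
  J <- det(F)
  if (J <= 0) {
    ff_stop("foamfem_negative_volume", "det(F) = %g <= 0: negative volume", J)
  }
  Ct <- crossprod(F)
  e <- eigen(Ct, symmetric = TRUE)
  lam <- sqrt(pmax(e$values, .Machine$double.eps))
  N <- e$vectors
  n <- sweep(F %*% N, 2L, lam, "/")
  structure(list(F = F, C = Ct, lambda = lam, N = N, n = n, J = J),
            class = "deformation_state")
}

as_state <- function(x) {
  if (inherits(x, "deformation_state")) return(x)
  if (is.matrix(x)) return(deformation_state(x))
  if (is.numeric(x) && length(x) == 3L) {
    # principal stretches on the Cartesian triad
    return(structure(list(F = diag(x), C = diag(x^2), lambda = as.numeric(x),
                          N = diag(3), n = diag(3), J = prod(x)),
                     class = "deformation_state"))
  }
  ff_stop("foamfem_invalid_deformation",
          "expected a deformation_state, a 3x3 F, or 3 principal stretches")
}

#' Hyperelastic foam strain-energy density
#'
#' Ogden-type compressible foam ("Hill functional", not to be confused with
#' 1D Hill-type contractile muscle models):
#' `Psi = sum_j (C_j/b_j) * (lambda_1^b_j + lambda_2^b_j + lambda_3^b_j - 3
#'  + (1/n)(J^(-n b_j) - 1))`,
#' with the `n = 0` penalty limit `-b_j log(J)`.
#'
#' @param state A [deformation_state()], a 3x3 `F`, or 3 principal stretches.
#' @param mat A [material_constants()] object.
#' @return Energy density (Pa). Zero at the reference state; invariant to
#'   permutation of the stretches; the penalty term vanishes for isochoric
#'   deformation (J = 1).
#' @export
hill_energy <- function(state, mat) {
  s <- as_state(state)
  lam <- s$lambda
  if (any(lam <= 0)) {
    ff_stop("foamfem_invalid_deformation", "non-positive principal stretch")
  }
  J <- s$J
  sum(mat$C / mat$b * (lam[1]^mat$b + lam[2]^mat$b + lam[3]^mat$b - 3 +
                         vapply(mat$b, function(bj) penalty_bracket(J, mat$n, bj),
                                numeric(1))))
}

#' Principal Cauchy stresses of the foam material
#'
#' `sigma_a = J^-1 lambda_a dPsi/dlambda_a`, which for each Ogden term
#' reduces to the closed form `C_j J^-1 (lambda_a^b_j - J^(-n b_j))`.
#'
#' @inheritParams hill_energy
#' @return Numeric length-3 vector of principal Cauchy stresses (Pa), in the
#'   order of `state$lambda`.
#' @export
principal_stresses <- function(state, mat) {
  s <- as_state(state)
  lam <- s$lambda
  if (any(lam <= 0)) {
    ff_stop("foamfem_invalid_deformation", "non-positive principal stretch")
  }
  J <- s$J
  Jp <- J^(-mat$n * mat$b)        # length m
  vapply(lam, function(la) sum(mat$C * (la^mat$b - Jp)) / J, numeric(1))
}

#' Assemble the Cauchy stress tensor from principal values and directions
#'
#' Spectral assembly `sigma = sum_a sigma_a n_a (x) n_a`.
#'
#' @param sigma Length-3 principal Cauchy stresses (Pa).
#' @param n 3x3 matrix whose columns are the orthonormal spatial principal
#'   directions (checked to 1e-8).
#' @return Symmetric 3x3 Cauchy stress tensor.
#' @export
assemble_cauchy_stress <- function(sigma, n) {
  sigma <- as.numeric(sigma)
  n <- as.matrix(n)
  if (length(sigma) != 3L || !all(dim(n) == c(3L, 3L))) {
    ff_stop("foamfem_invalid_argument", "need 3 principal values and a 3x3 triad")
  }
  if (max(abs(crossprod(n) - diag(3))) > 1e-8) {
    ff_stop("foamfem_invalid_triad", "principal directions are not orthonormal to 1e-8")
  }
  S <- n %*% (sigma * t(n))
  (S + t(S)) / 2
}

#' Full Cauchy stress for a deformation state
#'
#' Convenience wrapper: principal stresses plus spectral assembly on the
#' spatial triad.
#'
#' @inheritParams hill_energy
#' @return Symmetric 3x3 Cauchy stress tensor (Pa).
#' @export
cauchy_stress <- function(state, mat) {
  s <- as_state(state)
  assemble_cauchy_stress(principal_stresses(s, mat), s$n)
}

# Lateral-contraction exponent q such that the zero-lateral-stress uniaxial
# solution is lambda_lat = lambda_axial^(-q); q = n / (1 + 2n). Under the
# standard convention q == nu exactly.
lateral_exponent <- function(mat) mat$n / (1 + 2 * mat$n)

#' Lateral stretch under uniaxial stress
#'
#' Solves the zero-lateral-stress condition `sigma_2 = sigma_3 = 0` for the
#' lateral stretch. The analytic solution `lambda_lat =
#' lambda_axial^(-n/(1+2n))` (independent of the Ogden exponents) is
#' returned by default; `method = "root"` solves the equilibrium condition
#' numerically instead, as an independent check.
#'
#' @param lambda_axial Axial stretch(es), > 0.
#' @param mat A `foam_material`.
#' @param method `"closed_form"` (default) or `"root"`.
#' @return Lateral stretch(es).
#' @export
lateral_stretch <- function(lambda_axial, mat, method = c("closed_form", "root")) {
  method <- match.arg(method)
  lam <- as.numeric(lambda_axial)
  if (any(lam <= 0)) ff_stop("foamfem_invalid_argument", "lambda_axial must be > 0")
  q <- lateral_exponent(mat)
  if (method == "closed_form") return(lam^(-q))
  vapply(lam, function(la) {
    # residual of the lateral principal Cauchy stress at stretch exp(x)
    fn <- function(x) {
      ll <- exp(x)
      J <- la * ll^2
      sum(mat$C * (ll^mat$b - J^(-mat$n * mat$b)))
    }
    # Newton from the analytic guess: the residual can have several roots
    # for mixed-sign exponent sets, and the physical branch is the one
    # continuous with the analytic solution
    x <- -q * log(la)
    h <- 1e-7
    converged <- FALSE
    for (it in 1:100) {
      fx <- fn(x)
      dfx <- (fn(x + h) - fn(x - h)) / (2 * h)
      if (!is.finite(fx) || !is.finite(dfx) || dfx == 0) break
      step <- fx / dfx
      x <- x - step
      if (abs(step) < 1e-13) { converged <- TRUE; break }
    }
    if (!converged || !is.finite(fn(x))) {
      ff_stop("foamfem_no_lateral_solution",
              "no real lateral solution at lambda_axial = %g (invalid constants?)", la)
    }
    exp(x)
  }, numeric(1))
}

#' Uniaxial engineering (nominal) stress of the foam material
#'
#' Under uniaxial stress the lateral stretches satisfy `sigma_2 = sigma_3 =
#' 0`; with `lambda_lat = lambda^(-q)`, `q = n/(1+2n)`, the nominal stress
#' (Cauchy * J / lambda) reduces per term to
#' `C_j (lambda^(b_j - 1) - lambda^(-q b_j - 1))`. Under the standard
#' convention `q = nu`.
#'
#' @param lambda_axial Axial stretch(es), > 0.
#' @param mat A `foam_material`.
#' @param method `"closed_form"` (default) or `"root"` to obtain the lateral
#'   stretch from numerical equilibrium.
#' @return Engineering stress(es) (Pa).
#' @export
uniaxial_nominal_stress <- function(lambda_axial, mat,
                                    method = c("closed_form", "root")) {
  method <- match.arg(method)
  lam <- as.numeric(lambda_axial)
  if (any(lam <= 0)) ff_stop("foamfem_invalid_argument", "lambda_axial must be > 0")
  ll <- lateral_stretch(lam, mat, method = method)
  J <- lam * ll^2
  vapply(seq_along(lam), function(i) {
    sig1 <- sum(mat$C * (lam[i]^mat$b - J[i]^(-mat$n * mat$b))) / J[i]
    sig1 * J[i] / lam[i]
  }, numeric(1))
}

# Design matrix of the linear-in-C_j least-squares fit: column j evaluates
# the per-term uniaxial nominal stress at unit C_j.
uniaxial_design_matrix <- function(lambda, b, q) {
  X <- outer(lambda, b, function(la, bj) la^(bj - 1) - la^(-q * bj - 1))
  matrix(X, nrow = length(lambda))
}

#' Fit Ogden coefficients to an engineering stress-strain curve
#'
#' The uniaxial nominal stress is linear in the coefficients `C_j` for a
#' fixed exponent set `b_j`, so the curve-to-constants conversion is an
#' ordinary least-squares problem on the SFO-scaled ordinates. Doubling SFO
#' exactly doubles every fitted coefficient.
#'
#' @param curve A [load_curve()].
#' @param nu Poisson ratio in [0, 0.5).
#' @param exponents Ogden exponent set `b_j` (distinct, nonzero). Default
#'   `c(1, 2, 4, -1, -2)`, a small symmetric basis that captures convex
#'   tension curves and compression stiffening.
#' @param convention Penalty convention, see [penalty_exponent()].
#' @param max_rms_frac Refuse fits whose RMS residual exceeds this fraction
#'   of the peak absolute scaled stress (default 0.05) unless
#'   `allow_poor_fit = TRUE`.
#' @param allow_poor_fit Keep a poor fit (with a warning) instead of failing.
#' @return A list with `C`, `b`, `rms`, `rms_frac`, `fitted`, `residuals`.
#' @seealso [curve_material()] which wraps the fit into a `foam_material`.
#' @export
fit_constants_to_curve <- function(curve, nu, exponents = c(1, 2, 4, -1, -2),
                                   convention = c("standard", "paper"),
                                   max_rms_frac = 0.05, allow_poor_fit = FALSE) {
  convention <- match.arg(convention)
  if (!inherits(curve, "load_curve")) {
    ff_stop("foamfem_invalid_curve", "'curve' must be a load_curve")
  }
  b <- as.numeric(exponents)
  if (any(b == 0) || anyDuplicated(b)) {
    ff_stop("foamfem_rank_deficient", "exponents must be distinct and nonzero")
  }
  eps <- curve_strain(curve)
  y <- curve_stress(curve)
  if (length(eps) < length(b)) {
    ff_stop("foamfem_invalid_curve",
            "need at least as many curve samples (%d) as exponents (%d)",
            length(eps), length(b))
  }
  n <- penalty_exponent(nu, convention)
  q <- n / (1 + 2 * n)
  lam <- 1 + eps
  if (any(lam <= 0)) ff_stop("foamfem_invalid_curve", "strains must keep 1 + strain > 0")
  X <- uniaxial_design_matrix(lam, b, q)
  qrX <- qr(X)
  C <- qr.coef(qrX, y)
  if (anyNA(C)) {
    # numerically collinear basis (e.g. every term is ~linear at small
    # strain): keep the pivoted solution, zero the dropped columns
    ff_log("info", "collinear exponent basis: ",
           sum(is.na(C)), " term(s) dropped from the fit")
    C[is.na(C)] <- 0
  }
  fitted <- drop(X %*% C)
  res <- y - fitted
  rms <- sqrt(mean(res^2))
  peak <- max(abs(y))
  rms_frac <- if (peak > 0) rms / peak else 0
  if (rms_frac > max_rms_frac) {
    msg <- sprintf("curve fit RMS %.3g Pa is %.1f%% of peak stress (limit %.1f%%)",
                   rms, 100 * rms_frac, 100 * max_rms_frac)
    if (!allow_poor_fit) ff_stop("foamfem_poor_fit", "%s", msg)
    warning(msg)
  }
  list(C = as.numeric(C), b = b, rms = rms, rms_frac = rms_frac,
       fitted = fitted, residuals = res)
}

#' Build a curve-driven foam material
#'
#' Converts an engineering stress-strain load curve (or a strain-rate table
#' of curves) plus card constants into a `foam_material` whose Ogden
#' coefficients are least-squares fitted via [fit_constants_to_curve()].
#' For a rate table, coefficients are prefitted at every tabulated rate;
#' at run time they are interpolated linearly in log(rate) (equivalent to
#' interpolating the curve ordinates, because the fit is linear in the
#' ordinates) and clamped outside the tabulated range.
#'
#' @param curve A [load_curve()] or a [rate_table()].
#' @param density,K,G,nu,mu,sigf,convention,id Card fields, see
#'   [material_constants()].
#' @param exponents,max_rms_frac,allow_poor_fit Fit controls, see
#'   [fit_constants_to_curve()].
#' @return A `foam_material` carrying the source curve and fit diagnostics.
#' @export
curve_material <- function(curve, density, K, G, nu,
                           exponents = c(1, 2, 4, -1, -2),
                           mu = 0, sigf = 0,
                           convention = c("standard", "paper"),
                           max_rms_frac = 0.05, allow_poor_fit = FALSE,
                           id = 1L) {
  convention <- match.arg(convention)
  if (inherits(curve, "rate_table")) {
    fits <- lapply(curve$curves, function(cv) {
      fit_constants_to_curve(cv, nu, exponents, convention,
                             max_rms_frac, allow_poor_fit)
    })
    Cmat <- do.call(rbind, lapply(fits, `[[`, "C"))
    mat <- material_constants(density, K, G, nu, C = fits[[1L]]$C,
                              b = as.numeric(exponents), mu = mu, sigf = sigf,
                              convention = convention, id = id)
    mat$rate_fit <- list(rates = curve$rates, log_rates = log(curve$rates),
                         C = Cmat)
    mat$curve <- curve
    mat$fit <- fits[[1L]]
    return(mat)
  }
  fit <- fit_constants_to_curve(curve, nu, exponents, convention,
                                max_rms_frac, allow_poor_fit)
  mat <- material_constants(density, K, G, nu, C = fit$C, b = fit$b,
                            mu = mu, sigf = sigf, convention = convention,
                            id = id)
  mat$curve <- curve
  mat$fit <- fit
  mat
}

# Effective Ogden coefficients at a given smoothed strain rate: linear
# interpolation of the prefitted C_j in log(rate), clamped at the ends.
material_at_rate <- function(mat, rate) {
  rf <- mat$rate_fit
  if (is.null(rf)) return(mat)
  lr <- rf$log_rates
  if (rate <= rf$rates[1L]) {
    Ci <- rf$C[1L, ]
  } else if (rate >= rf$rates[length(lr)]) {
    Ci <- rf$C[nrow(rf$C), ]
  } else {
    x <- log(rate)
    i <- findInterval(x, lr)
    w <- (x - lr[i]) / (lr[i + 1L] - lr[i])
    Ci <- (1 - w) * rf$C[i, ] + w * rf$C[i + 1L, ]
  }
  mat$C <- as.numeric(Ci)
  mat$rate_fit <- NULL
  mat
}

#' Small-strain Young's modulus implied by the Ogden terms
#'
#' Tangent of the uniaxial nominal stress at the reference state:
#' `E = sum_j C_j b_j (1 + q)`, with `q` the lateral-contraction exponent
#' (`q = nu` under the standard convention).
#'
#' @param mat A `foam_material`.
#' @return Young's modulus (Pa).
#' @export
tangent_young_modulus <- function(mat) {
  q <- lateral_exponent(mat)
  sum(mat$C * mat$b) * (1 + q)
}
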