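# Shared stand-in soft-tissue constants. The licensed human-body-model
# tissue curves cannot be shipped, so every fixture uses a synthetic,
# clearly-labelled stand-in: a single-term Ogden foam with C = 8 kPa,
# b = 4, nu = 0.3 (small-strain Young's modulus ~41.6 kPa, in the range of
# relaxed human muscle), density 1050 kg/m^3.
FIXTURE_C <- 8e3
FIXTURE_B <- 4
FIXTURE_NU <- 0.3
FIXTURE_RHO <- 1050
FIXTURE_E <- FIXTURE_C * FIXTURE_B * (1 + FIXTURE_NU)          # ~41.6 kPa
# Card KM is deliberately much larger than E: real tissue cards carry a
# near-incompressible (water-like) bulk modulus that is used only for the
# CFL time step and contact stiffness, which keeps the explicit step well
# below the critical step of the (much softer) deviatoric response even at
# SFO = 10. 25x E is a desk-scale compromise between that realism and run
# time.
FIXTURE_K <- 25 * FIXTURE_E                                    # card KM
FIXTURE_G <- FIXTURE_E / (2 * (1 + FIXTURE_NU))                # card G

#' Synthetic stand-in soft-tissue load curve
#'
#' A convex engineering stress-strain curve sampled from a single-term
#' compressible foam (C = 8 kPa, b = 4, nu = 0.3). It stands in for
#' licensed tissue data and matches no real material.
#'
#' @param sfo Ordinate scale factor.
#' @param strain_max Largest sampled strain, default 0.6.
#' @param n_samples Number of samples, default 25.
#' @return A [load_curve()].
#' @export
default_soft_tissue_curve <- function(sfo = 1, strain_max = 0.6, n_samples = 25) {
  eps <- seq(0, strain_max, length.out = n_samples)
  lam <- 1 + eps
  b <- FIXTURE_B; nu <- FIXTURE_NU
  stress <- FIXTURE_C * (lam^(b - 1) - lam^(-nu * b - 1))
  load_curve(eps, stress, sfo = sfo)
}

#' Synthetic strain-rate table emulating rate-dependent passive muscle
#'
#' Three rates with ordinates scaled 1x / 2x / 4x over the stand-in curve,
#' qualitatively mirroring rate-stiffening passive muscle data; purely
#' synthetic.
#'
#' @param sfo Ordinate scale applied to every curve.
#' @param rates Strain rates (1/s), default `c(0.5, 5, 25)`.
#' @param factors Stiffness multipliers per rate, default `c(1, 2, 4)`.
#' @return A [rate_table()].
#' @export
default_rate_table <- function(sfo = 1, rates = c(0.5, 5, 25),
                               factors = c(1, 2, 4)) {
  base <- default_soft_tissue_curve(sfo = 1)
  rate_table(rates, lapply(factors, function(f) {
    load_curve(curve_strain(base), curve_stress(base) * f, sfo = sfo)
  }))
}

fixture_material <- function(source = NULL, sfo = 1, scale_card = FALSE,
                             density = FIXTURE_RHO, id = 1L) {
  if (is.null(source)) source <- default_soft_tissue_curve(sfo = sfo)
  if (inherits(source, "load_curve") && source$sfo != sfo) {
    source <- load_curve(source$strain, source$stress, sfo = sfo)
  }
  card <- if (scale_card) sfo else 1
  # even exponent basis: exact for the b = 4 stand-in curve and lets the
  # solver assemble stress as a polynomial in the left Cauchy-Green tensor
  # (no per-Gauss-point eigendecomposition)
  curve_material(source, density = density,
                 K = FIXTURE_K * card, G = FIXTURE_G * card,
                 nu = FIXTURE_NU, exponents = c(2, 4, -2), id = id)
}

fixture_manifest <- function(model, name, params, seed = NULL) {
  attr(model, "manifest") <- list(fixture = name, parameters = params,
                                  seed = seed, unit_system = "si")
  model
}

#' The 8-element cuboid verification model
#'
#' A 2 x 2 x 2 block of 1 mm hex elements with no loading, run for 50 ms
#' with CFL-auto time stepping. The card moduli KM/G are kept fixed across
#' SFO values (as the source human-body-model cards do), so the time step
#' and hence the cycle count are identical for every material variant.
#'
#' @param material Optional [load_curve()] or [rate_table()]; default the
#'   stand-in soft-tissue curve.
#' @param sfo Ordinate scale factor.
#' @param termination Termination time (s), default 0.050.
#' @return An [fe_model()] with manifest attribute.
#' @export
make_cuboid8 <- function(material = NULL, sfo = 1, termination = 0.050) {
  mesh <- box_mesh(c(2e-3, 2e-3, 2e-3), c(2L, 2L, 2L))
  mat <- fixture_material(material, sfo = sfo, scale_card = FALSE)
  cfg <- sim_config(termination = termination, dt = "auto", safety = 0.9,
                    output_interval = 1e-3)
  model <- fe_model(mesh, list(`1` = mat),
                    part_meta = data.frame(part = 1L, label = "soft",
                                           side = "center"),
                    config = cfg)
  fixture_manifest(model, "cuboid8", list(sfo = sfo, termination = termination))
}

#' Single-element uniaxial tension coupon
#'
#' A unit-dimension (1 mm) element with the axial displacement of both end
#' faces prescribed (fixed / slow smooth ramp) and free lateral faces, run
#' quasi-statically under fixed-step mass scaling with near-critical
#' mass-proportional damping.
#'
#' Two deliberate choices make the SFO response an exact scalar family:
#' the card moduli scale with SFO (the CFL estimate should track the true
#' tangent stiffness), and the nominal base density is tiny so that
#' fixed-step mass scaling always governs the density - making scaled mass
#' proportional to SFO and the nodal trajectories identical across SFO.
#'
#' @param material Optional [load_curve()]; default stand-in curve.
#' @param sfo Ordinate scale factor.
#' @param strain_max Target engineering strain, default 0.5.
#' @param dt Fixed time step (s), default 2e-5.
#' @param speed_fraction Ramp speed as a fraction of the mass-scaled wave
#'   speed, default 5e-4 (quasi-static).
#' @return An [fe_model()] with manifest attribute.
#' @export
make_uniaxial_coupon <- function(material = NULL, sfo = 1, strain_max = 0.5,
                                 dt = 2e-5, speed_fraction = 5e-4) {
  L0 <- 1e-3
  mesh <- box_mesh(c(L0, L0, L0), c(1L, 1L, 1L))
  mat <- fixture_material(material, sfo = sfo, scale_card = TRUE, density = 1)
  safety <- 0.9
  c_scaled <- L0 / (dt / safety)          # wave speed after mass scaling
  v_max <- speed_fraction * c_scaled
  t_ramp_up <- 0.05 * strain_max * L0 / v_max
  termination <- strain_max * L0 / v_max + t_ramp_up / 2
  vfun <- function(t) {
    ifelse(t < t_ramp_up, v_max * sin(pi * t / (2 * t_ramp_up))^2, v_max)
  }
  fixed <- which(mesh$nodes[, 1] < L0 / 2)
  moving <- which(mesh$nodes[, 1] > L0 / 2)
  omega <- c_scaled / L0
  cfg <- sim_config(
    termination = termination, dt = list(dt2ms = dt), safety = safety,
    output_interval = termination / 100,
    prescribed = list(list(nodes = fixed, dof = 1L, velocity = 0),
                      list(nodes = moving, dof = 1L, velocity = vfun)),
    damping = 0.9 * omega)
  model <- fe_model(mesh, list(`1` = mat),
                    part_meta = data.frame(part = 1L, label = "soft",
                                           side = "center"),
                    config = cfg)
  fixture_manifest(model, "uniaxial_coupon",
                   list(sfo = sfo, strain_max = strain_max, dt = dt,
                        speed_fraction = speed_fraction))
}

#' Measured response of a finished coupon run
#'
#' @param run An `fe_run` of a [make_uniaxial_coupon()] model.
#' @return Data frame with `time`, `strain` (axial engineering strain),
#'   `nominal_stress` (axial end-face reaction / reference area, Pa) and
#'   `lateral_stretch` (current/reference width).
#' @export
coupon_response <- function(run) {
  L0 <- 1e-3
  nodes <- run$mesh$nodes
  moving <- which(nodes[, 1] > L0 / 2)
  strain <- apply(run$node$u[, moving, 1, drop = FALSE], 1L, mean) / L0
  force <- apply(run$node$f_int[, moving, 1, drop = FALSE], 1L, sum)
  ylo <- which(nodes[, 2] < L0 / 2); yhi <- which(nodes[, 2] > L0 / 2)
  width <- apply(run$node$u[, yhi, 2, drop = FALSE], 1L, mean) -
    apply(run$node$u[, ylo, 2, drop = FALSE], 1L, mean) + L0
  data.frame(time = run$time, strain = strain,
             nominal_stress = force / (L0 * L0),
             lateral_stretch = width / L0)
}

#' Soft block dropped on a rigid plane
#'
#' A 10 mm soft block (2 x 2 x 2 elements) with an initial downward
#' velocity impacting a rigid plane under penalty contact - a desk-scale
#' surrogate for seat/thigh contact. Card moduli scale with SFO so the CFL
#' step tracks the true stiffness; the contact penalty follows the scaled
#' card bulk modulus times face-area-over-length, keeping the contact
#' frequency in a fixed, stable ratio to the element frequency for every
#' stiffness state.
#'
#' @param material Optional [load_curve()] or [rate_table()].
#' @param sfo Ordinate scale factor.
#' @param impact_speed Initial downward speed (m/s), > 0 for an impact;
#'   default 3.
#' @param dims Block edge lengths (m), default 10 mm cube.
#' @param divisions Element divisions, default 2 x 2 x 2.
#' @param penalty_scale Contact penalty factor on `K * A_face / L`,
#'   default 0.03, chosen so the contact oscillator stays well
#'   resolved by the CFL step (about 14 steps per contact period), which
#'   keeps the energy-balance drift of the impact under 1 percent.
#' @param termination Simulated time (s), default 0.015.
#' @return An [fe_model()] with manifest attribute.
#' @export
make_drop_block <- function(material = NULL, sfo = 1, impact_speed = 3,
                            dims = c(0.01, 0.01, 0.01),
                            divisions = c(2L, 2L, 2L),
                            penalty_scale = 0.03, termination = 0.015) {
  if (impact_speed < 0) ff_stop("foamfem_invalid_argument", "impact_speed must be >= 0")
  gap <- 1e-4
  mesh <- box_mesh(dims, divisions, origin = c(0, 0, gap))
  mat <- fixture_material(material, sfo = sfo, scale_card = TRUE)
  Lc <- dims[3] / divisions[3]
  A <- (dims[1] / divisions[1]) * (dims[2] / divisions[2])
  # penalty follows the SFO-scaled card bulk so the contact frequency keeps
  # a fixed ratio to the element frequency (stable for every SFO)
  penalty <- penalty_scale * sfo * FIXTURE_K * A / Lc
  plane <- rigid_plane(point = c(0, 0, 0), normal = c(0, 0, 1),
                       penalty = penalty)
  cfg <- sim_config(termination = termination, dt = "auto", safety = 0.9,
                    output_interval = 1e-4, planes = list(plane),
                    initial_velocity = c(0, 0, -impact_speed))
  model <- fe_model(mesh, list(`1` = mat),
                    part_meta = data.frame(part = 1L, label = "muscle",
                                           side = "center"),
                    config = cfg)
  fixture_manifest(model, "drop_block",
                   list(sfo = sfo, impact_speed = impact_speed, dims = dims,
                        divisions = divisions, penalty_scale = penalty_scale,
                        termination = termination))
}

#' Seeded synthetic element histories
#'
#' Stand-in for externally produced element output: reproducible histories
#' with prescribed per-element peak effective strains (uniaxial
#' incompressible tensors, so the metrics module recovers the prescribed
#' peaks exactly) and optional plastic increments.
#'
#' @param seed Integer seed (recorded; drives all randomness).
#' @param n Number of elements, >= 1.
#' @param volume_range Range (m^3) for uniform element volumes.
#' @param peak_strains Either a length-n vector of peak effective strains
#'   or a range to draw from uniformly.
#' @param plastic_fraction Fraction of elements that also receive constant
#'   plastic increments (per-step magnitude `plastic_step`).
#' @param plastic_step Effective plastic strain increment per step.
#' @param n_times Number of time samples, default 50.
#' @param labels,sides Optional per-element tissue/side labels (recycled).
#' @return List of [element_history()] objects; attribute `"manifest"`
#'   records the generator inputs.
#' @export
make_synthetic_histories <- function(seed, n, volume_range = c(1e-9, 3e-9),
                                     peak_strains = c(0.2, 0.8),
                                     plastic_fraction = 0.5,
                                     plastic_step = 1e-3,
                                     n_times = 50L,
                                     labels = "muscle", sides = "center") {
  if (n < 1L) ff_stop("foamfem_invalid_argument", "n must be >= 1")
  set.seed(as.integer(seed))
  vols <- stats::runif(n, volume_range[1], volume_range[2])
  peaks <- if (length(peak_strains) == n) {
    peak_strains                       # explicit per-element peaks
  } else if (length(peak_strains) == 2L) {
    stats::runif(n, peak_strains[1], peak_strains[2])
  } else {
    rep_len(peak_strains, n)
  }
  plastic <- seq_len(n) <= round(plastic_fraction * n)
  time <- seq(0, 0.05, length.out = n_times)
  shape <- sin(pi * seq(0, 1, length.out = n_times))^2   # rises then falls
  shape <- shape / max(shape)            # peak hit exactly on any grid
  labels <- rep_len(labels, n); sides <- rep_len(sides, n)
  E_fake <- 4e4
  hs <- lapply(seq_len(n), function(i) {
    e_ax <- peaks[i] * shape
    strain <- cbind(e_ax, -e_ax / 2, -e_ax / 2, 0, 0, 0)
    stress <- strain * E_fake
    pinc <- NULL
    if (plastic[i]) {
      d <- plastic_step
      pinc <- matrix(rep(c(d, -d / 2, -d / 2, 0, 0, 0), each = n_times),
                     n_times, 6L)
      pinc[1L, ] <- 0
    }
    element_history(id = i, time = time, stress = stress, strain = strain,
                    plastic_increment = pinc, volume = vols[i], part = i,
                    label = labels[i], side = sides[i])
  })
  attr(hs, "manifest") <- list(fixture = "synthetic_histories",
                               seed = seed, n = n,
                               volume_range = volume_range,
                               peak_strains = peaks,
                               plastic_fraction = plastic_fraction,
                               plastic_step = plastic_step,
                               n_times = n_times, unit_system = "si")
  hs
}
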