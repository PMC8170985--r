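# ---- lumped mass, CFL time step, selective mass scaling ------------------

# Accept a single material (recycled) or a per-element list.
resolve_materials <- function(materials, n_elem) {
  if (inherits(materials, "foam_material")) {
    return(rep(list(materials), n_elem))
  }
  if (is.list(materials) && length(materials) == n_elem) return(materials)
  ff_stop("foamfem_invalid_argument",
          "'materials' must be a foam_material or a per-element list (length %d)", n_elem)
}

element_densities <- function(materials, n_elem) {
  vapply(resolve_materials(materials, n_elem), `[[`, numeric(1), "density")
}

#' Lumped nodal masses
#'
#' Row-sum lumping of the hex8 consistent mass, i.e. each element
#' contributes `rho * V / 8` to each of its nodes; the total lumped mass
#' equals `sum(rho_e * V_e)` exactly.
#'
#' @param mesh An [fe_mesh()].
#' @param materials A `foam_material` or per-element list.
#' @param densities Optional per-element density override (kg/m^3), e.g.
#'   after mass scaling.
#' @return Numeric vector of nodal masses (kg), strictly positive.
#' @export
lumped_mass <- function(mesh, materials, densities = NULL) {
  E <- nrow(mesh$elements)
  rho <- densities %||% element_densities(materials, E)
  if (any(rho <= 0)) ff_stop("foamfem_invalid_material", "element density must be > 0")
  M <- numeric(nrow(mesh$nodes))
  share <- rho * mesh$volumes / 8
  for (e in seq_len(E)) {
    idx <- mesh$elements[e, ]
    M[idx] <- M[idx] + share[e]
  }
  M
}

# Dilatational wave speed from the card moduli: c = sqrt((K + 4G/3)/rho)
wave_speed <- function(K, G, rho) sqrt((K + 4 * G / 3) / rho)

#' CFL-critical time step
#'
#' Per-element characteristic length `L = volume / largest face area`, wave
#' speed `c = sqrt((K + 4G/3)/rho)` from the card moduli, critical step
#' `L/c`, and the global step `safety * min(L/c)`.
#'
#' @param mesh An [fe_mesh()].
#' @param materials A `foam_material` or per-element list.
#' @param safety Safety factor in (0, 1], default 0.9.
#' @param u Optional nodal displacements; lengths are then measured on the
#'   current geometry.
#' @param densities Optional per-element density override (after scaling).
#' @return A `timestep_info` list: `L`, `c`, `dt_crit` (per element),
#'   `dt` (global), `safety`, `added_mass`, `added_mass_pct` (zero here;
#'   filled by [apply_mass_scaling()]).
#' @export
critical_timestep <- function(mesh, materials, safety = 0.9, u = NULL,
                              densities = NULL) {
  if (!is_scalar_num(safety) || safety <= 0 || safety > 1) {
    ff_stop("foamfem_invalid_argument", "safety must be in (0, 1]")
  }
  E <- nrow(mesh$elements)
  mats <- resolve_materials(materials, E)
  rho <- densities %||% vapply(mats, `[[`, numeric(1), "density")
  L <- element_char_length(mesh, u)
  cs <- vapply(seq_len(E), function(e) wave_speed(mats[[e]]$K, mats[[e]]$G, rho[e]),
               numeric(1))
  dt_crit <- L / cs
  structure(list(L = L, c = cs, dt_crit = dt_crit,
                 dt = safety * min(dt_crit), safety = safety,
                 added_mass = 0, added_mass_pct = 0),
            class = "timestep_info")
}

#' Selective mass scaling to reach a target time step
#'
#' Elements whose critical time step falls below `dt_target` get their
#' density multiplied by `(dt_target / dt_crit)^2` (equivalently, set to
#' `(dt_target / L)^2 (K + 4G/3)`), so that afterwards every element
#' satisfies `dt_crit >= dt_target`. Densities are never decreased. The
#' added mass is reported absolutely and as a percentage of the unscaled
#' total, the reporting convention used with dt2ms-style mass scaling.
#'
#' @param mesh An [fe_mesh()].
#' @param materials A `foam_material` or per-element list.
#' @param dt_target Target time step (s), > 0.
#' @param densities Optional starting per-element densities.
#' @param u Optional displacements for current-geometry lengths.
#' @return List with `densities` (per element), and `info`, a
#'   `timestep_info` recomputed after scaling with `added_mass` (kg) and
#'   `added_mass_pct` filled in.
#' @export
apply_mass_scaling <- function(mesh, materials, dt_target, densities = NULL,
                               u = NULL) {
  stopifnot_scalar(dt_target, "dt_target", positive = TRUE)
  E <- nrow(mesh$elements)
  mats <- resolve_materials(materials, E)
  rho0 <- element_densities(materials, E)
  rho <- densities %||% rho0
  L <- element_char_length(mesh, u)
  stiff <- vapply(mats, function(m) m$K + 4 * m$G / 3, numeric(1))
  rho_req <- (dt_target / L)^2 * stiff
  rho_new <- pmax(rho, rho_req)
  added <- sum((rho_new - rho0) * mesh$volumes)
  total <- sum(rho0 * mesh$volumes)
  info <- critical_timestep(mesh, materials, safety = 1, u = u,
                            densities = rho_new)
  info$added_mass <- added
  info$added_mass_pct <- added_mass_percent(added, total)
  list(densities = rho_new, info = info)
}

#' Added-mass percentage of a mass-scaling report
#'
#' @param added Mass added by scaling (kg), >= 0.
#' @param total Unscaled total mass of the setup (kg), > 0.
#' @return `100 * added / total`.
#' @export
added_mass_percent <- function(added, total) {
  stopifnot_scalar(total, "total", positive = TRUE)
  stopifnot_scalar(added, "added")
  100 * added / total
}

# ---- internal forces -----------------------------------------------------

sym_to_voigt <- function(S) c(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[2, 3], S[3, 1])

# Manual 3x3 determinant / inverse: the assembly hot path cannot afford
# det()/solve() dispatch overhead.
det3 <- function(A) {
  A[1] * (A[5] * A[9] - A[8] * A[6]) -
  A[4] * (A[2] * A[9] - A[8] * A[3]) +
  A[7] * (A[2] * A[6] - A[5] * A[3])
}

inv3 <- function(A, d) {
  matrix(c(A[5] * A[9] - A[8] * A[6], A[8] * A[3] - A[2] * A[9],
           A[2] * A[6] - A[5] * A[3],
           A[7] * A[6] - A[4] * A[9], A[1] * A[9] - A[7] * A[3],
           A[4] * A[3] - A[1] * A[6],
           A[4] * A[8] - A[7] * A[5], A[7] * A[2] - A[1] * A[8],
           A[1] * A[5] - A[4] * A[2]) / d, 3L, 3L)
}

# One pass over all elements/Gauss points: internal force vector and,
# optionally, volume-averaged element fields (Cauchy stress, Hencky strain,
# current volume, strain energy). Uses dN/dx = dN/dX F^-1 and
# dV_current = dV_ref * det(F) so only reference gradients are needed.
assemble_internal <- function(mesh, u, mats, rates = NULL, fields = FALSE) {
  E <- nrow(mesh$elements)
  x <- mesh$nodes + u
  f <- matrix(0, nrow(mesh$nodes), 3L)
  sig_out <- if (fields) matrix(0, E, 6L) else NULL
  strain_out <- if (fields) matrix(0, E, 6L) else NULL
  vol_out <- if (fields) numeric(E) else NULL
  eff_out <- if (fields) numeric(E) else NULL
  energy <- 0
  for (e in seq_len(E)) {
    mat <- mats[[e]]
    if (!is.null(mat$rate_fit)) {
      mat <- material_at_rate(mat, if (is.null(rates)) 0 else rates[e])
    }
    Cj <- mat$C; bj <- mat$b; nn <- mat$n
    # all-even exponent sets admit an eigen-free stress: sum_a lambda_a^b
    # n_a (x) n_a = B^(b/2) with B = F F^T
    even_b <- all(bj %% 2 == 0)
    idx <- mesh$elements[e, ]
    xe <- x[idx, , drop = FALSE]
    grads <- mesh$dNdX[[e]]
    fe <- matrix(0, 8L, 3L)
    sig_acc <- matrix(0, 3L, 3L); hen_acc <- matrix(0, 3L, 3L); vol <- 0
    for (g in 1:8) {
      F <- crossprod(xe, grads[[g]])
      J <- det3(F)
      if (!is.finite(J) || J <= 0) {
        ff_stop("foamfem_negative_volume",
                "negative volume in element %d (gauss point %d)", e, g,
                data = list(element = e))
      }
      pen <- sum(Cj * J^(-nn * bj))
      if (even_b && !fields) {
        B <- tcrossprod(F)
        S <- diag(-pen, 3L)
        Binv <- NULL
        for (j in seq_along(bj)) {
          p <- bj[j] / 2
          if (p > 0) {
            Mp <- B
            if (p > 1) for (k in seq_len(p - 1)) Mp <- Mp %*% B
          } else {
            if (is.null(Binv)) Binv <- inv3(B, J * J)
            Mp <- Binv
            if (p < -1) for (k in seq_len(-p - 1)) Mp <- Mp %*% Binv
          }
          S <- S + Cj[j] * Mp
        }
        S <- (S + t(S)) * (0.5 / J)
        dVc <- mesh$dV[e, g] * J
        fe <- fe + (grads[[g]] %*% (inv3(F, J) %*% S)) * dVc
        next
      }
      ev <- eigen(crossprod(F), symmetric = TRUE)
      lam <- sqrt(pmax.int(ev$values, 1e-300))
      nvec <- (F %*% ev$vectors) * rep(1 / lam, each = 3L)
      lam_b <- lam^rep(bj, each = 3L)          # 3 x m (column-major)
      dim(lam_b) <- c(3L, length(bj))
      sig_p <- (drop(lam_b %*% Cj) - pen) / J
      S <- nvec %*% (sig_p * t(nvec))
      S <- (S + t(S)) * 0.5
      dVc <- mesh$dV[e, g] * J
      fe <- fe + (grads[[g]] %*% (inv3(F, J) %*% S)) * dVc
      if (fields) {
        sig_acc <- sig_acc + S * dVc
        H <- nvec %*% (log(lam) * t(nvec))
        hen_acc <- hen_acc + (H + t(H)) * 0.5 * dVc
        vol <- vol + dVc
        if (nn == 0) {
          penE <- sum(Cj * (-log(J)))
        } else {
          penE <- sum(Cj / bj * (J^(-nn * bj) - 1) / nn)
        }
        energy <- energy +
          (sum(Cj / bj * (colSums(lam_b) - 3)) + penE) * mesh$dV[e, g]
      }
    }
    f[idx, ] <- f[idx, ] + fe
    if (fields) {
      sig_out[e, ] <- sym_to_voigt(sig_acc / vol)
      strain_out[e, ] <- sym_to_voigt(hen_acc / vol)
      vol_out[e] <- vol
      eff_out[e] <- effective_strain(voigt_to_sym(strain_out[e, ]))
    }
  }
  list(f = f, sigma = sig_out, strain = strain_out, volume = vol_out,
       eff_strain = eff_out, energy = energy)
}

#' Internal nodal forces
#'
#' Gauss quadrature of `B^T sigma` over each element on the current
#' configuration, assembled to the nodes. Self-equilibrated: the forces sum
#' to zero over an unconstrained body.
#'
#' @param mesh An [fe_mesh()].
#' @param u N x 3 nodal displacements (m).
#' @param materials A `foam_material` or per-element list.
#' @return N x 3 matrix of internal forces (N).
#' @export
internal_forces <- function(mesh, u, materials) {
  mats <- resolve_materials(materials, nrow(mesh$elements))
  assemble_internal(mesh, u, mats)$f
}

# ---- rigid plane penalty contact ----------------------------------------

#' Define a rigid plane for penalty contact
#'
#' @param point A point on the plane (m).
#' @param normal Outward unit normal (pointing toward the body).
#' @param penalty Penalty stiffness (N/m per node), > 0.
#' @return A `rigid_plane` object.
#' @export
rigid_plane <- function(point, normal, penalty) {
  normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (abs(nn - 1) > 1e-8) {
    ff_stop("foamfem_invalid_argument", "plane normal must be unit length")
  }
  stopifnot_scalar(penalty, "penalty", positive = TRUE)
  structure(list(point = as.numeric(point), normal = normal / nn,
                 penalty = penalty), class = "rigid_plane")
}

#' Rigid-plane penalty contact forces
#'
#' Nodes penetrating the plane receive a restoring force along the outward
#' normal, proportional to the penetration depth.
#'
#' @param x N x 3 current nodal positions (m).
#' @param plane A [rigid_plane()].
#' @return List with `forces` (N x 3) and `resultant` (length-3 total
#'   contact force, zero when nothing penetrates).
#' @export
rigid_plane_contact <- function(x, plane) {
  n <- plane$normal
  depth <- drop((plane$point %*% n)[1] - x %*% n)   # > 0 means penetrated
  f <- matrix(0, nrow(x), 3L)
  pen <- depth > 0
  if (any(pen)) {
    f[pen, ] <- (plane$penalty * depth[pen]) %o% n
  }
  list(forces = f, resultant = colSums(f))
}

# ---- central-difference integration --------------------------------------

#' Nodal kinematic state
#'
#' @param u,v N x 3 displacements and velocities. Inside the solver the
#'   stored velocity lives on the staggered half step `t - dt_prev/2`.
#' @param M Lumped nodal masses (kg), strictly positive.
#' @param t Current time (s).
#' @param dt_prev Previous step size (0 before the first step, which makes
#'   the first velocity update the standard initial half step).
#' @return A `nodal_state` object (also carries the last acceleration `a`).
#' @export
nodal_state <- function(u, v, M, t = 0, dt_prev = 0) {
  if (any(M <= 0)) ff_stop("foamfem_invalid_argument", "nodal masses must be positive")
  structure(list(u = u, v = v, a = matrix(0, nrow(u), 3L), M = M,
                 t = t, dt_prev = dt_prev), class = "nodal_state")
}

#' One explicit central-difference step
#'
#' `a = (f_ext - f_int)/M` componentwise (minus optional mass-proportional
#' damping), velocities advanced over the staggered half steps, then
#' displacements; prescribed-motion degrees of freedom are overridden after
#' the update.
#'
#' @param state A [nodal_state()].
#' @param f_int,f_ext N x 3 force matrices (N).
#' @param dt Time step (s).
#' @param damping Mass-proportional damping coefficient (1/s), default 0.
#' @param prescribed List of prescribed motions, each a list with `nodes`
#'   (indices), `dof` (1..3) and `velocity` (a function of time, or a
#'   constant).
#' @return The updated `nodal_state`; attribute `"constraint_work"` holds
#'   the work increment done through the prescribed constraints.
#' @export
central_difference_step <- function(state, f_int, f_ext, dt, damping = 0,
                                    prescribed = NULL) {
  if (!all(is.finite(f_int)) || !all(is.finite(f_ext))) {
    ff_stop("foamfem_instability", "non-finite force encountered at t = %g s", state$t)
  }
  dtbar <- 0.5 * (state$dt_prev + dt)
  f <- f_ext - f_int - damping * (state$M * state$v)
  a <- f / state$M
  v_new <- state$v + a * dtbar
  w_con <- 0
  if (length(prescribed)) {
    t_half <- state$t + dt / 2
    for (p in prescribed) {
      vp <- if (is.function(p$velocity)) p$velocity(t_half) else p$velocity
      idx <- cbind(p$nodes, p$dof)
      # reaction work: force needed to realize the override minus what the
      # free dynamics would have supplied
      v_free <- v_new[idx]
      v_new[idx] <- vp
      if (dtbar > 0) {
        r <- state$M[p$nodes] * (vp - v_free) / dtbar
        w_con <- w_con + sum(r * (vp + state$v[idx]) / 2) * dtbar
      }
    }
  }
  u_new <- state$u + v_new * dt
  out <- state
  out$u <- u_new; out$v <- v_new; out$a <- a
  out$t <- state$t + dt; out$dt_prev <- dt
  attr(out, "constraint_work") <- w_con
  out
}

# ---- simulation driver ---------------------------------------------------

#' Simulation configuration
#'
#' @param termination Termination time (s), > 0.
#' @param dt Time-step policy: `"auto"` (CFL each cycle) or a list
#'   `list(dt2ms = <target in s>)` for fixed-step selective mass scaling,
#'   mirroring a negative dt2ms on a timestep-control card.
#' @param safety CFL safety factor in (0, 1], default 0.9.
#' @param output_interval Time between history frames (s).
#' @param planes List of [rigid_plane()] contact definitions.
#' @param gravity Length-3 gravity vector (m/s^2), default zero.
#' @param prescribed List of prescribed motions (see
#'   [central_difference_step()]).
#' @param damping Mass-proportional damping coefficient (1/s), default 0.
#' @param initial_velocity Length-3 vector applied to all nodes, or an
#'   N x 3 matrix.
#' @param rate_tau Time constant (s) of the exponential moving average used
#'   to smooth the effective-strain rate for rate-table lookup; default
#'   1e-4 s (0.1 ms).
#' @param seed Integer recorded in the manifest (the solver itself is
#'   deterministic).
#' @param max_energy_ratio Flag the run as unstable when the kinetic energy
#'   exceeds this multiple of the reference energy scale (default 10).
#' @return A `sim_config` object.
#' @export
sim_config <- function(termination, dt = "auto", safety = 0.9,
                       output_interval = NULL, planes = list(),
                       gravity = c(0, 0, 0), prescribed = list(),
                       damping = 0, initial_velocity = NULL,
                       rate_tau = 1e-4, seed = NULL,
                       max_energy_ratio = 10) {
  stopifnot_scalar(termination, "termination", positive = TRUE)
  output_interval <- output_interval %||% (termination / 100)
  stopifnot_scalar(output_interval, "output_interval", positive = TRUE)
  structure(list(termination = termination, dt = dt, safety = safety,
                 output_interval = output_interval, planes = planes,
                 gravity = as.numeric(gravity), prescribed = prescribed,
                 damping = damping, initial_velocity = initial_velocity,
                 rate_tau = rate_tau, seed = seed,
                 max_energy_ratio = max_energy_ratio),
            class = "sim_config")
}

#' Finite-element model: mesh + materials + configuration
#'
#' @param mesh An [fe_mesh()].
#' @param materials Named list of `foam_material`s keyed by material id.
#' @param part_materials Named integer map part id -> material id. Default:
#'   every part uses the first material.
#' @param part_meta Optional data.frame with columns `part`, `label`
#'   (tissue label) and `side` used by the injury grouping.
#' @param config A [sim_config()].
#' @return An `fe_model`.
#' @export
fe_model <- function(mesh, materials, part_materials = NULL, part_meta = NULL,
                     config = NULL) {
  if (inherits(materials, "foam_material")) materials <- list(materials)
  names(materials) <- names(materials) %||%
    vapply(materials, function(m) as.character(m$id), character(1))
  parts <- sort(unique(mesh$part))
  if (is.null(part_materials)) {
    part_materials <- stats::setNames(rep(materials[[1L]]$id, length(parts)),
                                      as.character(parts))
  }
  if (is.null(part_meta)) {
    part_meta <- data.frame(part = parts, label = "soft", side = "center",
                            stringsAsFactors = FALSE)
  }
  structure(list(mesh = mesh, materials = materials,
                 part_materials = part_materials, part_meta = part_meta,
                 config = config), class = "fe_model")
}

model_element_materials <- function(model) {
  mid <- model$part_materials[as.character(model$mesh$part)]
  lapply(as.character(mid), function(id) model$materials[[id]])
}

#' Run an explicit-dynamics simulation
#'
#' Central-difference time loop with CFL-auto or fixed (mass-scaled) time
#' stepping, penalty contact against rigid planes, optional gravity,
#' prescribed motions and mass-proportional damping. Histories (element
#' stress/strain/volume, nodal kinematics and internal forces, contact
#' resultants, energy audit) are recorded at the configured output
#' interval. The run is deterministic: identical model and seed give
#' bitwise-identical histories.
#'
#' Early termination on negative element volume or detected instability
#' does not discard results: the returned object carries the frames
#' computed so far and a `termination_status` of `"negative_volume"` or
#' `"unstable"` plus the offending message.
#'
#' @param model An [fe_model()] whose `config` is set, or pass `config`.
#' @param config Optional [sim_config()] overriding `model$config`.
#' @return An `fe_run` object: `time` (frame times), `element` (arrays
#'   `stress`, `strain` `[frame, element, 6]`, `volume` `[frame, element]`),
#'   `node` (`u`, `v`, `f_int` arrays `[frame, node, 3]`), `contact`
#'   (data.frame time/fx/fy/fz/magnitude), `energy` (data.frame with
#'   kinetic, internal, external work, damping and constraint work, and
#'   `balance_error`), and `manifest` (dt policy, cycles, added mass,
#'   termination status, seed).
#' @export
run_simulation <- function(model, config = NULL) {
  cfg <- config %||% model$config
  if (is.null(cfg)) ff_stop("foamfem_invalid_argument", "no sim_config supplied")
  mesh <- model$mesh
  mats <- model_element_materials(model)
  E <- nrow(mesh$elements); N <- nrow(mesh$nodes)
  has_rate <- any(vapply(mats, function(m) !is.null(m$rate_fit), logical(1)))

  rho0 <- vapply(mats, `[[`, numeric(1), "density")
  rho <- rho0
  fixed_dt <- NULL
  if (is.list(cfg$dt) && !is.null(cfg$dt$dt2ms)) {
    ms <- apply_mass_scaling(mesh, mats, cfg$dt$dt2ms / cfg$safety)
    rho <- ms$densities
    fixed_dt <- cfg$dt$dt2ms
  } else if (!identical(cfg$dt, "auto")) {
    ff_stop("foamfem_invalid_argument", "dt policy must be \"auto\" or list(dt2ms = ...)")
  }
  M <- lumped_mass(mesh, mats, densities = rho)
  total_mass0 <- sum(rho0 * mesh$volumes)
  added_mass <- sum((rho - rho0) * mesh$volumes)

  v0 <- matrix(0, N, 3L)
  if (!is.null(cfg$initial_velocity)) {
    iv <- cfg$initial_velocity
    v0 <- if (is.matrix(iv)) iv else matrix(iv, N, 3L, byrow = TRUE)
  }
  state <- nodal_state(u = matrix(0, N, 3L), v = v0, M = M)
  stiff <- vapply(mats, function(m) m$K + 4 * m$G / 3, numeric(1))
  rate_ema <- numeric(E); prev_eff <- numeric(E)

  n_guess <- ceiling(cfg$termination / cfg$output_interval) + 2L
  time_v <- numeric(n_guess)
  stress_a <- array(NA_real_, c(n_guess, E, 6L))
  strain_a <- array(NA_real_, c(n_guess, E, 6L))
  volume_m <- matrix(NA_real_, n_guess, E)
  u_a <- array(NA_real_, c(n_guess, N, 3L))
  v_a <- array(NA_real_, c(n_guess, N, 3L))
  fint_a <- array(NA_real_, c(n_guess, N, 3L))
  contact_m <- matrix(NA_real_, n_guess, 3L)
  energy_m <- matrix(NA_real_, n_guess, 6L)
  nframe <- 0L

  W_ext <- 0; W_damp <- 0; W_int <- 0
  prev_u <- state$u; prev_fint <- NULL; prev_fext <- NULL; prev_fdamp <- NULL
  KE0 <- 0.5 * sum(M * rowSums(v0^2))
  E_ref <- max(KE0, .Machine$double.eps)
  status <- "normal"; status_msg <- NULL
  cycles <- 0L
  next_out <- 0
  rescan <- 8L
  dt_base <- NA_real_

  run_loop <- function() {
    repeat {
      output_due <- state$t >= next_out - 1e-12
      asm <- assemble_internal(mesh, state$u, mats,
                               rates = if (has_rate) rate_ema else NULL,
                               fields = output_due || has_rate)
      x <- mesh$nodes + state$u
      f_ext <- matrix(cfg$gravity, N, 3L, byrow = TRUE) * state$M
      contact_res <- c(0, 0, 0)
      for (pl in cfg$planes) {
        ct <- rigid_plane_contact(x, pl)
        f_ext <- f_ext + ct$forces
        contact_res <- contact_res + ct$resultant
      }
      f_damp <- cfg$damping * (state$M * state$v)
      # trapezoidal work increments (the standard explicit-solver energy
      # bookkeeping): pair mean force over the step with the displacement
      # increment
      if (cycles > 0L) {
        du <- state$u - prev_u
        W_int <<- W_int + 0.5 * sum((prev_fint + asm$f) * du)
        W_ext <<- W_ext + 0.5 * sum((prev_fext + f_ext) * du)
        W_damp <<- W_damp + 0.5 * sum((prev_fdamp + f_damp) * du)
      }
      prev_u <<- state$u; prev_fint <<- asm$f; prev_fext <<- f_ext
      prev_fdamp <<- f_damp
      if (output_due) {
        nframe <<- nframe + 1L
        # time-centered velocity for reporting: the stored v lives on the
        # staggered half step, which would make KE accurate only to O(dt)
        a_now <- (f_ext - asm$f) / state$M - cfg$damping * state$v
        v_ctr <- state$v + 0.5 * state$dt_prev * a_now
        KE <- 0.5 * sum(state$M * rowSums(v_ctr^2))
        time_v[nframe] <<- state$t
        stress_a[nframe, , ] <<- asm$sigma
        strain_a[nframe, , ] <<- asm$strain
        volume_m[nframe, ] <<- asm$volume
        u_a[nframe, , ] <<- state$u
        v_a[nframe, , ] <<- state$v
        fint_a[nframe, , ] <<- asm$f
        contact_m[nframe, ] <<- contact_res
        bal <- KE + W_int + W_damp - W_ext - KE0
        energy_m[nframe, ] <<- c(KE, asm$energy, W_int, W_ext, W_damp, bal)
        E_ref <<- max(E_ref, abs(W_ext), asm$energy)
        if (KE > cfg$max_energy_ratio * E_ref && KE > 1e-12) {
          ff_stop("foamfem_instability",
                  "kinetic energy %.3g J exceeds %g x reference energy %.3g J at t = %g s",
                  KE, cfg$max_energy_ratio, E_ref, state$t)
        }
        next_out <<- next_out + cfg$output_interval
      }
      if (state$t >= cfg$termination - 1e-12) break

      # geometry-dependent step control is rescanned every few cycles; the
      # CFL safety factor covers the slow drift of element lengths between
      # rescans
      if (cycles %% rescan == 0L) {
        L <- element_char_length(mesh, state$u)
        if (is.null(fixed_dt)) {
          dt_base <<- cfg$safety * min(L * sqrt(rho / stiff))
        } else {
          # continuous selective mass scaling: keep every element's
          # critical step at or above target/safety on current geometry
          rho_req <- (fixed_dt / cfg$safety / L)^2 * stiff
          bump <- rho_req > rho
          if (any(bump)) {
            rho[bump] <<- rho_req[bump]
            M <<- lumped_mass(mesh, mats, densities = rho)
            state$M <<- M
            added_mass <<- sum((rho - rho0) * mesh$volumes)
          }
          dt_base <<- fixed_dt
        }
      }
      dt <- dt_base
      dt <- min(dt, cfg$termination - state$t, next_out - state$t)
      dt <- max(dt, 1e-15)

      state <<- central_difference_step(state, asm$f, f_ext, dt,
                                        damping = cfg$damping,
                                        prescribed = cfg$prescribed)
      cycles <<- cycles + 1L
      # work done through prescribed constraints counts as external
      W_ext <<- W_ext + attr(state, "constraint_work")
      if (has_rate) {
        inst <- abs(asm$eff_strain - prev_eff) / dt
        alpha <- 1 - exp(-dt / cfg$rate_tau)
        rate_ema <<- rate_ema + alpha * (inst - rate_ema)
        prev_eff <<- asm$eff_strain
      }
    }
  }

  err <- tryCatch({ run_loop(); NULL },
                  foamfem_negative_volume = function(e) e,
                  foamfem_instability = function(e) e)
  if (!is.null(err)) {
    status <- if (inherits(err, "foamfem_negative_volume")) "negative_volume" else "unstable"
    status_msg <- conditionMessage(err)
    ff_log("warn", "run terminated early (", status, "): ", status_msg)
  }

  keep <- seq_len(nframe)
  energy <- as.data.frame(energy_m[keep, , drop = FALSE])
  names(energy) <- c("kinetic", "internal", "internal_work", "external_work",
                     "dissipated_work", "balance_error")
  energy <- cbind(time = time_v[keep], energy)
  contact <- as.data.frame(contact_m[keep, , drop = FALSE])
  names(contact) <- c("fx", "fy", "fz")
  contact <- cbind(time = time_v[keep], contact)
  contact$magnitude <- sqrt(contact$fx^2 + contact$fy^2 + contact$fz^2)

  structure(list(
    time = time_v[keep],
    element = list(stress = stress_a[keep, , , drop = FALSE],
                   strain = strain_a[keep, , , drop = FALSE],
                   volume = volume_m[keep, , drop = FALSE]),
    node = list(u = u_a[keep, , , drop = FALSE],
                v = v_a[keep, , , drop = FALSE],
                f_int = fint_a[keep, , , drop = FALSE]),
    contact = contact,
    energy = energy,
    mesh = mesh, model = model,
    manifest = list(
      dt_policy = if (is.null(fixed_dt)) "auto" else "dt2ms",
      dt = fixed_dt, safety = cfg$safety, cycles = cycles,
      added_mass = added_mass,
      added_mass_pct = added_mass_percent(added_mass, total_mass0),
      termination_status = status, status_message = status_msg,
      termination_time = cfg$termination, end_time = time_v[nframe],
      seed = cfg$seed %||% NA_integer_, unit_system = "si")
  ), class = "fe_run")
}

#' @export
print.fe_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<fe_run> %s after %d cycles (t = %g s), %d frames, dt policy %s\n",
              m$termination_status, m$cycles, m$end_time, length(x$time),
              m$dt_policy))
  if (m$added_mass > 0) {
    cat(sprintf("  mass scaling: +%.4g kg (%.3g%%)\n", m$added_mass, m$added_mass_pct))
  }
  invisible(x)
}
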