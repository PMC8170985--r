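# Voigt convention used throughout: (xx, yy, zz, xy, yz, zx), tensor
# components (not engineering shear).
voigt_to_sym <- function(v) {
  matrix(c(v[1], v[4], v[6],
           v[4], v[2], v[5],
           v[6], v[5], v[3]), 3L, 3L)
}

as_sym_tensor <- function(x) {
  if (is.matrix(x) && all(dim(x) == c(3L, 3L))) {
    if (max(abs(x - t(x))) > 1e-8 * max(1, max(abs(x)))) {
      ff_stop("foamfem_invalid_argument", "tensor must be symmetric")
    }
    return((x + t(x)) / 2)
  }
  if (is.numeric(x) && length(x) == 6L) return(voigt_to_sym(x))
  ff_stop("foamfem_invalid_argument",
          "expected a symmetric 3x3 matrix or a length-6 Voigt vector")
}

#' Effective (von Mises) stress
#'
#' `sigma_eff = sqrt(((s1-s2)^2 + (s1-s3)^2 + (s2-s3)^2) / 2)` on the
#' principal values, equal to `sqrt(3 J2)` of the stress deviator.
#'
#' @param sigma Symmetric 3x3 stress tensor, a length-6 Voigt vector
#'   (xx, yy, zz, xy, yz, zx), or a length-3 vector of principal stresses.
#' @return Scalar effective stress (same units as the input).
#' @export
effective_stress <- function(sigma) {
  if (is.numeric(sigma) && length(sigma) == 3L && !is.matrix(sigma)) {
    p <- sigma
    return(sqrt(((p[1] - p[2])^2 + (p[1] - p[3])^2 + (p[2] - p[3])^2) / 2))
  }
  S <- as_sym_tensor(sigma)
  dev <- S - diag(mean(diag(S)), 3L)
  sqrt(1.5 * sum(dev * dev))
}

#' Effective strain
#'
#' `eps_eff = sqrt((2/3) * eps_ij eps_ij)`, the full tensor contraction
#' (off-diagonal components counted twice). For a uniaxial-incompressible
#' state `diag(e, -e/2, -e/2)` it returns `e`.
#'
#' @param eps Symmetric 3x3 strain tensor or length-6 Voigt vector.
#' @return Scalar effective strain (dimensionless, >= 0).
#' @export
effective_strain <- function(eps) {
  Etens <- as_sym_tensor(eps)
  sqrt(2 / 3 * sum(Etens * Etens))
}

#' Spatial logarithmic (Hencky) strain
#'
#' `sum_a log(lambda_a) n_a (x) n_a` on the spatial principal triad; its
#' trace equals `log(J)`.
#'
#' @param F A 3x3 deformation gradient or a [deformation_state()].
#' @return Symmetric 3x3 strain tensor.
#' @export
log_strain <- function(F) {
  s <- as_state(F)
  H <- s$n %*% (log(s$lambda) * t(s$n))
  (H + t(H)) / 2
}

#' Per-element time history
#'
#' The standalone post-processing container: time samples with symmetric
#' stress and strain tensors (Voigt rows), optional plastic-strain
#' increment tensors, and element metadata.
#'
#' @param id Element id.
#' @param time Strictly increasing time samples (s).
#' @param stress,strain T x 6 matrices, Voigt order (xx, yy, zz, xy, yz, zx).
#' @param plastic_increment Optional T x 6 matrix of per-step plastic strain
#'   increment tensors.
#' @param volume Reference element volume (m^3), > 0.
#' @param part Part id.
#' @param label Tissue label: `"muscle"`, `"soft"`, `"cortical"`,
#'   `"spongy"` or `"other"`.
#' @param side Body side label (e.g. `"left"`, `"right"`, `"center"`).
#' @return An `element_history` object.
#' @export
element_history <- function(id, time, stress, strain,
                            plastic_increment = NULL, volume = 1,
                            part = 1L, label = "other", side = "center") {
  time <- as.numeric(time)
  if (length(time) < 1L || any(diff(time) <= 0)) {
    ff_stop("foamfem_invalid_history", "time must be non-empty and strictly increasing")
  }
  fix <- function(m, nm) {
    m <- as.matrix(m)
    if (nrow(m) != length(time) || ncol(m) != 6L) {
      ff_stop("foamfem_invalid_history", "%s must be T x 6 (Voigt)", nm)
    }
    m
  }
  stress <- fix(stress, "stress"); strain <- fix(strain, "strain")
  if (!is.null(plastic_increment)) plastic_increment <- fix(plastic_increment, "plastic_increment")
  stopifnot_scalar(volume, "volume", positive = TRUE)
  structure(list(id = id, part = part, label = label, side = side,
                 volume = volume, time = time, stress = stress,
                 strain = strain, plastic_increment = plastic_increment),
            class = "element_history")
}

#' Extract element histories from a finished run
#'
#' @param run An `fe_run` from [run_simulation()].
#' @return List of [element_history()] objects (reference volumes; labels
#'   and sides resolved through the model's part metadata).
#' @export
as_element_histories <- function(run) {
  mesh <- run$mesh
  meta <- run$model$part_meta
  lapply(seq_len(nrow(mesh$elements)), function(e) {
    p <- mesh$part[e]
    row <- meta[meta$part == p, , drop = FALSE]
    element_history(
      id = e, time = run$time,
      stress = run$element$stress[, e, , drop = TRUE],
      strain = run$element$strain[, e, , drop = TRUE],
      volume = mesh$volumes[e], part = p,
      label = if (nrow(row)) row$label[1L] else "other",
      side = if (nrow(row)) row$side[1L] else "center")
  })
}

#' Effective stress / strain series of an element history
#'
#' @param h An [element_history()].
#' @return Numeric series, one value per time sample.
#' @export
history_effective_strain <- function(h) {
  apply(h$strain, 1L, effective_strain)
}

#' @rdname history_effective_strain
#' @export
history_effective_stress <- function(h) {
  apply(h$stress, 1L, effective_stress)
}

#' Accumulated effective plastic strain
#'
#' Running sum of `sqrt((2/3) d_eps^p : d_eps^p)` over the recorded
#' plastic-strain increments; identically zero (with a logged notice) when
#' the history carries no plastic increments.
#'
#' @param history An [element_history()].
#' @return Non-decreasing numeric time series, one value per time sample.
#' @export
effective_plastic_strain <- function(history) {
  if (!inherits(history, "element_history")) {
    ff_stop("foamfem_invalid_history", "'history' must be an element_history")
  }
  if (is.null(history$plastic_increment)) {
    ff_log("info", "element ", history$id,
           ": no plastic increments recorded; returning zeros")
    return(numeric(length(history$time)) * 0)
  }
  inc <- apply(history$plastic_increment, 1L, function(v) {
    effective_strain(v)   # same sqrt(2/3 x:x) contraction per increment
  })
  cumsum(inc)
}

#' Linear-fit Young's modulus from effective stress-strain history
#'
#' Ordinary least squares of effective stress against effective strain
#' restricted to the "timespan of highest loading": by default the
#' contiguous run of samples around the stress peak where the effective
#' stress is at least `frac` (25%) of its peak.
#'
#' @param stress,strain Equal-length numeric series (effective values).
#' @param window Either `"auto"` (default) or a length-2 numeric giving
#'   index bounds into the series.
#' @param frac Peak fraction defining the auto window, default 0.25.
#' @return A `stiffness_fit` list: `modulus` (slope, Pa), `intercept`,
#'   `r_squared`, `window` (index bounds), `n`.
#' @export
fit_young_modulus <- function(stress, strain, window = "auto", frac = 0.25) {
  stress <- as.numeric(stress); strain <- as.numeric(strain)
  if (length(stress) != length(strain) || length(stress) < 3L) {
    ff_stop("foamfem_invalid_argument", "need >= 3 paired samples")
  }
  if (identical(window, "auto")) {
    pk <- which.max(stress)
    lim <- frac * stress[pk]
    lo <- pk; while (lo > 1L && stress[lo - 1L] >= lim) lo <- lo - 1L
    hi <- pk; while (hi < length(stress) && stress[hi + 1L] >= lim) hi <- hi + 1L
    window <- c(lo, hi)
  }
  window <- as.integer(window)
  if (length(window) != 2L || window[1L] < 1L || window[2L] > length(stress) ||
      diff(window) < 2L) {
    ff_stop("foamfem_invalid_argument", "window must select >= 3 samples in range")
  }
  idx <- window[1L]:window[2L]
  x <- strain[idx]; y <- stress[idx]
  if (stats::var(x) <= 0) {
    ff_stop("foamfem_degenerate_window", "zero strain variance in fit window")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  ybar <- mean(y)
  ss_tot <- sum((y - ybar)^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  structure(list(modulus = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 r_squared = r2, window = window, n = length(idx)),
            class = "stiffness_fit")
}

#' @export
print.stiffness_fit <- function(x, ...) {
  cat(sprintf("<stiffness_fit> E = %.6g Pa (R^2 = %.4f, %d samples, window %d..%d)\n",
              x$modulus, x$r_squared, x$n, x$window[1], x$window[2]))
  invisible(x)
}
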