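#' Force-based injury risk curve
#'
#' A pluggable force -> probability lookup (the numeric parameters of
#' published hip/knee AIS2+ curves are user-supplied, not shipped).
#'
#' @param force Strictly increasing forces (N).
#' @param probability Non-decreasing probabilities in [0, 1].
#' @param label Curve label, e.g. `"hip AIS2+"`.
#' @return A `risk_curve` object.
#' @export
risk_curve <- function(force, probability, label = "risk") {
  force <- as.numeric(force); probability <- as.numeric(probability)
  if (length(force) < 1L || length(force) != length(probability)) {
    ff_stop("foamfem_invalid_risk_curve", "force and probability must be equal-length")
  }
  if (any(diff(force) <= 0)) {
    ff_stop("foamfem_invalid_risk_curve", "forces must be strictly increasing")
  }
  if (any(probability < 0 | probability > 1) || any(diff(probability) < 0)) {
    ff_stop("foamfem_invalid_risk_curve",
            "probabilities must be non-decreasing within [0, 1]")
  }
  structure(list(force = force, probability = probability, label = label),
            class = "risk_curve")
}

#' Probability lookup on a risk curve
#'
#' Linear interpolation between tabulated points; forces outside the domain
#' clamp to the end probabilities.
#'
#' @param curve A [risk_curve()].
#' @param force Force value(s) (N).
#' @return Probability in [0, 1] per force.
#' @export
risk_lookup <- function(curve, force) {
  if (!inherits(curve, "risk_curve")) {
    ff_stop("foamfem_invalid_risk_curve", "'curve' must be a risk_curve")
  }
  if (length(curve$force) == 1L) return(rep(curve$probability, length(force)))
  stats::approx(curve$force, curve$probability, xout = force, rule = 2)$y
}

#' Peak of a resultant force series
#'
#' @param force Numeric force magnitudes.
#' @param time Matching time samples.
#' @return List `value` (maximum magnitude) and `time` (first attainment).
#' @export
peak_force <- function(force, time = seq_along(force)) {
  force <- abs(as.numeric(force))
  if (!length(force)) ff_stop("foamfem_invalid_argument", "empty force series")
  i <- which.max(force)   # which.max returns the first maximum
  list(value = force[i], time = time[i])
}

#' First principal strain
#'
#' @param eps Symmetric 3x3 strain tensor or length-6 Voigt vector.
#' @return Largest eigenvalue.
#' @export
first_principal_strain <- function(eps) {
  max(eigen(as_sym_tensor(eps), symmetric = TRUE, only.values = TRUE)$values)
}

#' Lower-bound strain threshold from failure statistics
#'
#' Tensile tests of muscle tissue report the maximum elongation as a mean
#' with a standard deviation; the damage-measure threshold is the lower
#' limit `mean - sd`. The canonical inputs 95% +/- 36% give 59%.
#'
#' @param mean_elongation Mean failure elongation (strain fraction or
#'   percent, as long as both arguments share units).
#' @param sd_elongation Standard deviation, `0 <= sd < mean`.
#' @return `mean_elongation - sd_elongation`.
#' @export
csdm_threshold_from_failure_stats <- function(mean_elongation, sd_elongation) {
  stopifnot_scalar(mean_elongation, "mean_elongation")
  stopifnot_scalar(sd_elongation, "sd_elongation")
  if (sd_elongation < 0 || mean_elongation <= sd_elongation) {
    ff_stop("foamfem_invalid_argument",
            "need mean > sd >= 0 (got mean %g, sd %g): threshold would be non-positive",
            mean_elongation, sd_elongation)
  }
  mean_elongation - sd_elongation
}

# Per-history scalar field series used by the accumulation criteria
history_field <- function(h, field) {
  switch(field,
         effective_strain = history_effective_strain(h),
         effective_plastic_strain = effective_plastic_strain(h),
         first_principal_strain = apply(h$strain, 1L, first_principal_strain),
         ff_stop("foamfem_invalid_argument", "unknown field '%s'", field))
}

# Common accumulation machinery: an element contributes its reference
# volume from the first sample where field > threshold onward.
accumulate_failed <- function(histories, field, threshold, accumulate = TRUE) {
  time <- histories[[1L]]$time
  vol <- numeric(length(time))
  failed_parts <- integer(0)
  for (h in histories) {
    if (!identical(length(h$time), length(time))) {
      ff_stop("foamfem_invalid_history", "histories must share a common time base")
    }
    s <- history_field(h, field)
    over <- s > threshold
    if (accumulate) {
      first <- match(TRUE, over)
      if (!is.na(first)) {
        vol[first:length(time)] <- vol[first:length(time)] + h$volume
        failed_parts <- union(failed_parts, h$part)
      }
    } else {
      vol[over] <- vol[over] + h$volume
      if (any(over)) failed_parts <- union(failed_parts, h$part)
    }
  }
  list(time = time, volume = vol, parts = failed_parts)
}

#' Failed-element volume time series
#'
#' Accumulates the reference volume of elements whose chosen strain field
#' strictly exceeds a threshold: once an element has failed it stays
#' counted ("accumulated over the entire computation time"). An
#' instantaneous (non-accumulating) mode is available for sensitivity
#' checks.
#'
#' @param histories List of [element_history()] objects on a common time
#'   base.
#' @param field One of `"effective_plastic_strain"`,
#'   `"first_principal_strain"`, `"effective_strain"`.
#' @param threshold Strain threshold (strict exceedance), e.g. 0.015 for
#'   the 1.5% bone criterion.
#' @param accumulate Once-failed-always-counted (default TRUE).
#' @return List with `time`, `volume` (non-decreasing when accumulating),
#'   `parts` (contributing part ids) and the `threshold`/`field` used.
#' @export
failed_element_volume <- function(histories,
                                  field = c("effective_plastic_strain",
                                            "first_principal_strain",
                                            "effective_strain"),
                                  threshold = 0.015, accumulate = TRUE) {
  field <- match.arg(field)
  if (!length(histories)) ff_stop("foamfem_invalid_argument", "no histories supplied")
  out <- accumulate_failed(histories, field, threshold, accumulate)
  c(out, list(threshold = threshold, field = field))
}

#' Cumulative strain damage measure (CSDM)
#'
#' Accumulated volume (and volume fraction) of elements whose effective
#' strain ever exceeds the threshold, grouped by tissue label and body
#' side. Default threshold 0.59, the lower limit of the reported muscle
#' failure elongation 95% +/- 36%.
#'
#' @param histories List of [element_history()] objects.
#' @param threshold Effective-strain threshold, default 0.59.
#' @param by Grouping columns among `"label"`, `"side"`; default both.
#' @return A list of per-group results, each with `time`, `volume`,
#'   `fraction` (volume / total group volume), `group_volume`, `label`,
#'   `side`; plus `threshold`.
#' @export
csdm <- function(histories, threshold = 0.59, by = c("label", "side")) {
  if (!length(histories)) {
    ff_log("info", "csdm: empty history set")
    return(structure(list(groups = list(), threshold = threshold), class = "csdm"))
  }
  key <- vapply(histories, function(h) {
    paste(vapply(by, function(k) as.character(h[[k]]), character(1)), collapse = "/")
  }, character(1))
  groups <- lapply(split(histories, key), function(hs) {
    acc <- accumulate_failed(hs, "effective_strain", threshold, TRUE)
    gv <- sum(vapply(hs, `[[`, numeric(1), "volume"))
    list(time = acc$time, volume = acc$volume, fraction = acc$volume / gv,
         group_volume = gv, label = hs[[1L]]$label, side = hs[[1L]]$side)
  })
  structure(list(groups = groups, threshold = threshold), class = "csdm")
}

#' @export
print.csdm <- function(x, ...) {
  cat(sprintf("<csdm> threshold %.3g, %d group(s)\n", x$threshold, length(x$groups)))
  for (nm in names(x$groups)) {
    g <- x$groups[[nm]]
    cat(sprintf("  %s: terminal volume %.4g m^3 (fraction %.3g)\n",
                nm, g$volume[length(g$volume)], g$fraction[length(g$fraction)]))
  }
  invisible(x)
}

#' Assemble an injury report
#'
#' Bundles the strain-based accumulation criteria with peak contact force
#' and force-based risk probabilities.
#'
#' @param histories List of [element_history()] objects.
#' @param contact Optional data.frame with `time` and `magnitude` columns
#'   (a contact resultant history).
#' @param risk_curves Optional list of [risk_curve()]s evaluated at the
#'   peak contact force.
#' @param thresholds Named numeric vector of failed-element-volume
#'   thresholds per field, default
#'   `c(effective_plastic_strain = 0.015, first_principal_strain = 0.015)`.
#' @param csdm_threshold Effective-strain threshold for [csdm()], default
#'   0.59.
#' @return An `injury_report` list: `failed` (per field), `csdm`,
#'   `peak_force`, `risk`.
#' @export
injury_report <- function(histories, contact = NULL, risk_curves = list(),
                          thresholds = c(effective_plastic_strain = 0.015,
                                         first_principal_strain = 0.015),
                          csdm_threshold = 0.59) {
  failed <- lapply(names(thresholds), function(f) {
    failed_element_volume(histories, field = f, threshold = thresholds[[f]])
  })
  names(failed) <- names(thresholds)
  pk <- NULL; risk <- NULL
  if (!is.null(contact) && nrow(contact)) {
    pk <- peak_force(contact$magnitude, contact$time)
    if (length(risk_curves)) {
      risk <- vapply(risk_curves, function(rc) risk_lookup(rc, pk$value), numeric(1))
      names(risk) <- vapply(risk_curves, `[[`, character(1), "label")
    }
  }
  structure(list(failed = failed, csdm = csdm(histories, csdm_threshold),
                 peak_force = pk, risk = risk),
            class = "injury_report")
}
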