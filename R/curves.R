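#' Engineering stress-strain load curve
#'
#' A load curve holds engineering-strain abscissae and engineering-stress
#' ordinates, plus the ordinate scale factor SFO used throughout this package
#' as the proxy for isometric-contraction stiffness state: the effective
#' ordinate is always `stress * sfo`. If the curve does not contain the
#' origin it is anchored by prepending a (0, 0) sample, since zero stress at
#' the reference configuration is an invariant of the material.
#'
#' @param strain Strictly increasing engineering strains (dimensionless).
#' @param stress Engineering stresses (Pa in SI), same length as `strain`.
#' @param sfo Ordinate scale factor (> 0), default 1.
#' @param sfa Abscissa scale factor (> 0), default 1; applied to `strain`
#'   at construction.
#' @return An object of class `load_curve`.
#' @examples
#' lc <- load_curve(c(0.1, 0.2), c(5e3, 12e3), sfo = 2)
#' curve_stress(lc)     # SFO-scaled ordinates, origin anchored
#' @export
load_curve <- function(strain, stress, sfo = 1, sfa = 1) {
  if (length(strain) != length(stress) || length(strain) < 1L) {
    ff_stop("foamfem_invalid_curve", "strain and stress must be equal-length, non-empty")
  }
  stopifnot_scalar(sfo, "sfo", positive = TRUE)
  stopifnot_scalar(sfa, "sfa", positive = TRUE)
  strain <- as.numeric(strain) * sfa
  stress <- as.numeric(stress)
  if (any(!is.finite(strain)) || any(!is.finite(stress))) {
    ff_stop("foamfem_invalid_curve", "curve samples must be finite")
  }
  if (any(diff(strain) <= 0)) {
    ff_stop("foamfem_invalid_curve", "curve abscissa must be strictly increasing")
  }
  if (!any(strain == 0)) {
    strain <- c(0, strain)
    stress <- c(0, stress)
    if (any(diff(strain) <= 0)) {
      ff_stop("foamfem_invalid_curve",
              "curve with negative strains must contain an explicit (0, 0) sample")
    }
  } else if (stress[strain == 0] != 0) {
    ff_stop("foamfem_invalid_curve", "stress at zero strain must be zero")
  }
  structure(list(strain = strain, stress = stress, sfo = sfo),
            class = "load_curve")
}

#' @rdname load_curve
#' @param curve A `load_curve`.
#' @export
curve_strain <- function(curve) curve$strain

#' @rdname load_curve
#' @export
curve_stress <- function(curve) curve$stress * curve$sfo

#' @export
print.load_curve <- function(x, ...) {
  cat(sprintf("<load_curve> %d samples, strain [%g, %g], SFO = %g\n",
              length(x$strain), min(x$strain), max(x$strain), x$sfo))
  invisible(x)
}

#' Strain-rate-keyed table of load curves
#'
#' Mirrors the table mechanism used to model strain-rate-dependent passive
#' muscle stiffness: a set of load curves keyed by strain rate. Lookups
#' between tabulated rates interpolate the SFO-scaled ordinates linearly
#' in log(rate); rates outside the tabulated range clamp to the nearest
#' curve.
#'
#' @param rates Strictly increasing, positive strain rates (1/s).
#' @param curves List of `load_curve`s, one per rate.
#' @return An object of class `rate_table`.
#' @export
rate_table <- function(rates, curves) {
  if (length(rates) < 2L) {
    ff_stop("foamfem_invalid_table", "a rate table needs at least 2 entries")
  }
  if (length(rates) != length(curves)) {
    ff_stop("foamfem_invalid_table", "rates and curves must have equal length")
  }
  rates <- as.numeric(rates)
  if (any(rates <= 0) || any(diff(rates) <= 0)) {
    ff_stop("foamfem_invalid_table", "rates must be positive and strictly increasing")
  }
  ok <- vapply(curves, inherits, logical(1), "load_curve")
  if (!all(ok)) ff_stop("foamfem_invalid_table", "all table entries must be load_curves")
  structure(list(rates = rates, curves = curves), class = "rate_table")
}

#' Select (or interpolate) the load curve for a strain rate
#'
#' @param table A [rate_table()].
#' @param rate Strain rate (1/s), >= 0.
#' @return A `load_curve` with SFO already folded into its ordinates
#'   (`sfo = 1`): exact tabulated rates return that curve's scaled samples;
#'   intermediate rates blend the two bracketing curves linearly in
#'   log(rate) on the union of their abscissae; out-of-range rates clamp.
#' @export
select_rate_curve <- function(table, rate) {
  if (!inherits(table, "rate_table")) {
    ff_stop("foamfem_invalid_table", "'table' must be a rate_table")
  }
  stopifnot_scalar(rate, "rate")
  if (rate < 0) ff_stop("foamfem_invalid_argument", "rate must be >= 0")
  r <- table$rates
  scaled <- function(cv) load_curve(curve_strain(cv), curve_stress(cv), sfo = 1)
  hit <- which(r == rate)
  if (length(hit)) return(scaled(table$curves[[hit[1L]]]))
  if (rate <= r[1L]) return(scaled(table$curves[[1L]]))
  if (rate >= r[length(r)]) return(scaled(table$curves[[length(r)]]))
  i <- findInterval(rate, r)
  lo <- table$curves[[i]]; hi <- table$curves[[i + 1L]]
  w <- (log(rate) - log(r[i])) / (log(r[i + 1L]) - log(r[i]))
  xs <- sort(unique(c(curve_strain(lo), curve_strain(hi))))
  ylo <- stats::approx(curve_strain(lo), curve_stress(lo), xout = xs, rule = 2)$y
  yhi <- stats::approx(curve_strain(hi), curve_stress(hi), xout = xs, rule = 2)$y
  load_curve(xs, (1 - w) * ylo + w * yhi, sfo = 1)
}
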