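#' Bead-based stiffness calibration curve
#'
#' Fits the log-linear standard curve `log10(E) = alpha + beta * D` between
#' the AFM-measured elastic moduli of calibration beads (kPa) and their
#' deformability measured in the device. Beads spanning roughly 0.2--40 kPa
#' are the intended calibration range; mapping a deformability outside the
#' fitted bead range is flagged as extrapolation.
#'
#' @param bead_D Numeric vector of bead deformabilities (>= 3 beads).
#' @param bead_E Positive elastic moduli (kPa), same length.
#' @return Object of class `calibration_curve`: `alpha`, `beta`,
#'   `r_squared`, `d_range`, `e_range` (kPa). Warns when the fit explains
#'   less than half the variance (R^2 < 0.5).
#' @export
fit_stiffness_calibration <- function(bead_D, bead_E) {
  stopifnot(length(bead_D) == length(bead_E))
  if (length(bead_D) < 3L) stopf("calibration needs at least 3 beads")
  if (any(bead_E <= 0)) stopf("elastic moduli must be positive")
  fit <- stats::lm(log10(bead_E) ~ bead_D)
  r2 <- r_squared(log10(bead_E), stats::fitted(fit))
  if (is.finite(r2) && r2 < 0.5)
    warnf("calibration fit is poor (R^2 = %.2f); check bead data", r2)
  co <- stats::coef(fit)
  structure(list(alpha = unname(co[1L]), beta = unname(co[2L]),
                 r_squared = r2,
                 d_range = range(bead_D), e_range = range(bead_E)),
            class = "calibration_curve")
}

#' Map deformability to effective stiffness
#'
#' @param curve A `calibration_curve`.
#' @param D Deformability value(s).
#' @return Effective elastic moduli in kPa, with logical attribute
#'   `extrapolated` marking values outside the fitted bead deformability
#'   range.
#' @export
map_stiffness <- function(curve, D) {
  stopifnot(inherits(curve, "calibration_curve"))
  e <- 10^(curve$alpha + curve$beta * D)
  extra <- D < curve$d_range[1L] | D > curve$d_range[2L]
  if (any(extra))
    warnf("%d value(s) outside the calibrated deformability range",
          sum(extra))
  attr(e, "extrapolated") <- extra
  e
}

#' Invert the calibration: stiffness back to deformability
#'
#' @param curve A `calibration_curve`.
#' @param E Elastic moduli in kPa (> 0).
#' @return Deformability value(s).
#' @export
invert_stiffness <- function(curve, E) {
  stopifnot(inherits(curve, "calibration_curve"), all(E > 0))
  if (abs(curve$beta) < .Machine$double.eps)
    stopf("flat calibration curve cannot be inverted")
  (log10(E) - curve$alpha) / curve$beta
}
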