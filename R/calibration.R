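#' System sensitivity calibration
#'
#' A calibration record holds the system sensitivity \eqn{Q} in counts per
#' second per MBq, with its standard uncertainty, determined from an
#' acquisition of a reference source of known activity.
#'
#' @param sensitivity Q in cps/MBq (> 0).
#' @param u_sensitivity standard uncertainty of Q (cps/MBq, >= 0).
#' @param nuclide radionuclide label (default `"I-131"`).
#' @param half_life_h physical half-life in hours (default I-131,
#'   8.0252 days).
#' @param reference_time optional timestamp string the sensitivity refers to.
#' @return An object of class `calibration`.
#' @export
calibration <- function(sensitivity, u_sensitivity = 0, nuclide = "I-131",
                        half_life_h = I131_HALF_LIFE_H, reference_time = NA_character_) {
  if (!is.finite(sensitivity) || sensitivity <= 0)
    stop("'sensitivity' must be > 0 cps/MBq")
  if (!is.finite(u_sensitivity) || u_sensitivity < 0)
    stop("'u_sensitivity' must be >= 0")
  structure(
    list(sensitivity = as.numeric(sensitivity),
         u_sensitivity = as.numeric(u_sensitivity),
         nuclide = nuclide, half_life_h = as.numeric(half_life_h),
         reference_time = reference_time),
    class = "calibration"
  )
}

#' I-131 physical half-life in hours (8.0252 days)
#' @export
I131_HALF_LIFE_H <- 8.0252 * 24

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: Q = %.4g +/- %.3g cps/MBq (%s, T1/2 = %.4g h)\n",
              x$sensitivity, x$u_sensitivity, x$nuclide, x$half_life_h))
  invisible(x)
}

#' Sensitivity factor from a reference-source acquisition
#'
#' Computes \eqn{Q = C_{VOI} / A_{capsule}}: the total count rate within an
#' oversized VOI enclosing all counts from a reference capsule, divided by
#' the capsule activity at the scan midpoint.  The relative uncertainty of Q
#' combines the count-rate and activity relative uncertainties in
#' quadrature.
#'
#' If `u_count_rate` is not supplied and `duration` is given, a Poisson
#' counting uncertainty is used: \eqn{u(C) = \sqrt{C \cdot T} / T}.
#'
#' @param voi_count_rate total VOI count rate, cps (> 0).
#' @param reference_activity capsule activity at the scan midpoint, MBq (> 0).
#' @param u_activity standard uncertainty of the reference activity, MBq.
#'   For a dose-calibrator measurement this is the quadrature combination of
#'   the standard deviation of the mean of repeated readings and the quoted
#'   calibrator-factor uncertainty (see [combine_activity_uncertainty()]).
#' @param u_count_rate standard uncertainty of the count rate (cps);
#'   if `NULL`, derived from Poisson statistics when `duration` is given,
#'   else taken as 0.
#' @param duration acquisition duration in seconds, used for the Poisson
#'   count-rate uncertainty.
#' @param ... passed to [calibration()] (`nuclide`, `half_life_h`,
#'   `reference_time`).
#' @return A [calibration] object.
#' @examples
#' sensitivity_factor(80.92, reference_activity = 2.8, u_activity = 0.028)
#' @export
sensitivity_factor <- function(voi_count_rate, reference_activity,
                               u_activity = 0, u_count_rate = NULL,
                               duration = NA_real_, ...) {
  if (!is.finite(reference_activity) || reference_activity <= 0)
    stop("'reference_activity' must be > 0 MBq")
  if (!is.finite(voi_count_rate) || voi_count_rate <= 0)
    stop("'voi_count_rate' must be > 0 cps (sensitivity must be positive)")
  if (is.null(u_count_rate)) {
    u_count_rate <- if (is.finite(duration) && duration > 0)
      sqrt(voi_count_rate * duration) / duration else 0
  }
  q <- voi_count_rate / reference_activity
  rel2 <- (u_count_rate / voi_count_rate)^2 + (u_activity / reference_activity)^2
  calibration(sensitivity = q, u_sensitivity = q * sqrt(rel2), ...)
}

#' Combine repeated-measurement and calibrator-factor uncertainties
#'
#' Standard uncertainty of a dose-calibrator activity measurement: the
#' standard deviation of the mean of repeated readings combined in
#' quadrature with the quoted relative uncertainty of the calibrator factor.
#'
#' @param readings vector of repeated activity readings (MBq).
#' @param rel_calibrator_u quoted relative standard uncertainty of the
#'   calibrator factor (e.g. 0.01 for 1 percent).
#' @return list with `activity` (mean, MBq) and `u_activity` (MBq).
#' @export
combine_activity_uncertainty <- function(readings, rel_calibrator_u = 0) {
  readings <- as.numeric(readings)
  if (length(readings) < 1L) stop("at least one reading required")
  m <- mean(readings)
  sem <- if (length(readings) > 1L) stats::sd(readings) / sqrt(length(readings)) else 0
  list(activity = m, u_activity = sqrt(sem^2 + (m * rel_calibrator_u)^2))
}

#' Radioactive decay correction
#'
#' Decays (or back-decays, for negative `delta_t_h`) an activity by
#' \eqn{A \cdot 2^{-\Delta t / T_{1/2}}}.
#'
#' @param activity activity in MBq.
#' @param delta_t_h elapsed time in hours (may be negative to reference an
#'   activity back to an earlier time).
#' @param half_life_h half-life in hours (> 0).
#' @return Decay-corrected activity in MBq.
#' @examples
#' decay_correct(10, delta_t_h = 24)           # I-131 default half-life
#' decay_correct(10, 192.6048, 192.6048)       # one half-life: exactly 5
#' @export
decay_correct <- function(activity, delta_t_h, half_life_h = I131_HALF_LIFE_H) {
  if (!is.finite(half_life_h) || half_life_h <= 0) stop("'half_life_h' must be > 0")
  activity * 2^(-delta_t_h / half_life_h)
}
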