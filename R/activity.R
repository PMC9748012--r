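#' Activity estimate container
#'
#' @param activity activity in MBq.
#' @param u_activity standard uncertainty in MBq (`NA` when the method does
#'   not provide one).
#' @param method one of `"concentric"`, `"local_voi"`,
#'   `"recovery_coefficient"`.
#' @param applied_recovery recovery coefficient applied (1 for oversized-VOI
#'   methods).
#' @param u_recovery standard uncertainty of the applied recovery.
#' @param gradient estimated background concentration (cps/ml), when known.
#' @param fit the underlying [fit_intercept()] object, when applicable.
#' @param warnings character vector of flags.
#' @return An object of class `activity_estimate`.
#' @export
activity_estimate <- function(activity, u_activity, method,
                              applied_recovery = 1, u_recovery = 0,
                              gradient = NA_real_, fit = NULL,
                              warnings = character(0)) {
  method <- match.arg(method, c("concentric", "local_voi", "recovery_coefficient"))
  structure(
    list(activity = activity, u_activity = u_activity, method = method,
         applied_recovery = applied_recovery, u_recovery = u_recovery,
         gradient = gradient, fit = fit, warnings = warnings),
    class = "activity_estimate"
  )
}

#' @export
print.activity_estimate <- function(x, ...) {
  cat(sprintf("activity estimate (%s method)\n", x$method))
  if (is.na(x$u_activity))
    cat(sprintf("  A = %.5g MBq (no uncertainty available for this method)\n", x$activity))
  else
    cat(sprintf("  A = %.5g +/- %.3g MBq (%.2f%%)\n", x$activity, x$u_activity,
                100 * x$u_activity / abs(x$activity)))
  if (x$applied_recovery != 1)
    cat(sprintf("  recovery applied: R = %.4g +/- %.3g\n", x$applied_recovery, x$u_recovery))
  if (is.finite(x$gradient))
    cat(sprintf("  background concentration: %.5g cps/ml\n", x$gradient))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Convert source counts to activity with propagated uncertainty
#'
#' \eqn{A = C / (Q R)}, with the law of propagation of uncertainty applied
#' to first order:
#' \deqn{[u(A)/A]^2 = [u(Q)/Q]^2 + [u(C)/C]^2 (+\, [u(R)/R]^2)}
#' The recovery term enters the quadrature only when a non-unit recovery
#' coefficient is applied (oversized-VOI methods use R = 1 exactly: all
#' source counts are inside the VOI and no recovery correction — nor its
#' uncertainty — is involved).
#'
#' Uncertainties are combined in absolute form, so a zero count rate still
#' yields a finite u(A).
#'
#' @param count_rate source count rate C in cps.
#' @param u_count_rate standard uncertainty of C (cps).
#' @param calibration a [calibration] object (Q, u(Q)).
#' @param recovery recovery coefficient R in (0, 1].
#' @param u_recovery standard uncertainty of R.
#' @param method method tag recorded in the result.
#' @param ... passed to [activity_estimate()].
#' @return An [activity_estimate].
#' @examples
#' cal <- calibration(28.9, 0.4)
#' activity_from_counts(578, 5.78, cal)       # ~20.0 +/- 0.34 MBq
#' @export
activity_from_counts <- function(count_rate, u_count_rate, calibration,
                                 recovery = 1, u_recovery = 0,
                                 method = "concentric", ...) {
  stopifnot(inherits(calibration, "calibration"))
  if (!is.finite(recovery) || recovery <= 0) stop("recovery R must be > 0")
  if (recovery > 1) stop("recovery R must be <= 1")
  q <- calibration$sensitivity
  A <- count_rate / (q * recovery)
  # absolute-form LPU: u(A)^2 = (uC/(QR))^2 + (A uQ/Q)^2 [+ (A uR/R)^2]
  u2 <- (u_count_rate / (q * recovery))^2 + (A * calibration$u_sensitivity / q)^2
  if (recovery < 1) u2 <- u2 + (A * u_recovery / recovery)^2
  activity_estimate(activity = A, u_activity = sqrt(u2), method = method,
                    applied_recovery = recovery, u_recovery = u_recovery, ...)
}

#' Quantify a small source with the concentric oversized-VOI method
#'
#' The full proposed chain: delineate `n_vois` concentric spherical VOIs
#' about the source, regress VOI count rate on VOI volume, take the
#' intercept as the source count rate with its closed-form uncertainty, and
#' convert to activity with R = 1 (the innermost VOI is oversized, so all
#' source counts are included and no recovery correction applies).
#'
#' The default VOI plan sizes the innermost sphere at 1.5 x the system PSF
#' FWHM — enclosing more than 99.5 percent of an isotropic 3D Gaussian — with
#' three further VOIs at 0.5-FWHM radius increments.
#'
#' @param image an [image_volume].
#' @param center source centre in physical mm coordinates.
#' @param calibration a [calibration] object.
#' @param psf_fwhm system resolution (FWHM, mm) used to size the default
#'   VOI plan; ignored when `base_radius`/`radius_step` are given.
#' @param base_radius innermost VOI radius (mm); default `1.5 * psf_fwhm`.
#' @param n_vois number of concentric VOIs (>= 3).
#' @param radius_step radius increment (mm); default `0.5 * psf_fwhm`.
#' @return An [activity_estimate] with the intercept fit attached
#'   (`$fit`) and the fitted background concentration (`$gradient`).
#' @export
quantify_concentric <- function(image, center, calibration,
                                psf_fwhm = 15, base_radius = NULL,
                                n_vois = 4L, radius_step = NULL) {
  if (is.null(base_radius)) base_radius <- 1.5 * psf_fwhm
  if (is.null(radius_step)) radius_step <- 0.5 * psf_fwhm
  series <- build_concentric_series(image, center, base_radius,
                                    n_vois = n_vois, radius_step = radius_step)
  fit <- fit_intercept(series)
  est <- activity_from_counts(fit$intercept, fit$u_intercept, calibration,
                              recovery = 1, method = "concentric",
                              gradient = fit$gradient, fit = fit,
                              warnings = fit$warnings)
  est
}

#' Quantify with an oversized VOI and a local background VOI
#'
#' Comparator method: an oversized VOI encloses all source counts
#' (\eqn{C_V}, volume \eqn{V_V}); a second VOI placed in nearby background
#' (\eqn{C_B}, volume \eqn{V_B}) estimates the background concentration,
#' whose contribution is subtracted volume-proportionally:
#' \deqn{A = \frac{C_V - (V_V / V_B)\, C_B}{Q R}, \quad R = 1.}
#' No uncertainty estimate is defined for this method; `u_activity` is
#' returned as `NA`.
#'
#' @param source_counts total count rate of the oversized source VOI (cps).
#' @param source_volume its volume (ml, > 0).
#' @param background_counts count rate of the local background VOI (cps).
#' @param background_volume its volume (ml, > 0).
#' @param calibration a [calibration] object.
#' @return An [activity_estimate] with `u_activity = NA`.
#' @examples
#' cal <- calibration(10)
#' quantify_local_voi(1000, 50, 200, 100, cal)   # 90 MBq
#' @export
quantify_local_voi <- function(source_counts, source_volume,
                               background_counts, background_volume,
                               calibration) {
  stopifnot(inherits(calibration, "calibration"))
  if (!is.finite(source_volume) || source_volume <= 0)
    stop("'source_volume' must be > 0")
  if (!is.finite(background_volume) || background_volume <= 0)
    stop("'background_volume' must be > 0")
  if (source_counts < 0 || background_counts < 0)
    stop("count rates must be >= 0")
  corrected <- source_counts - (source_volume / background_volume) * background_counts
  A <- corrected / calibration$sensitivity
  activity_estimate(activity = A, u_activity = NA_real_, method = "local_voi")
}
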