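#' Recovery factor for a single phantom insert
#'
#' The recovery coefficient of insert *i* is the ratio of the activity
#' apparent from the counts inside the matched anatomical VOI to the known
#' insert activity: \eqn{R_i = C_i / (Q A_i)}.  For a fully recovered
#' source \eqn{C_i = Q A_i} and \eqn{R_i = 1}.
#'
#' @param count_rate counts within the insert-matched VOI (cps).
#' @param known_activity true insert activity (MBq, > 0).
#' @param calibration a [calibration] object.
#' @return Unitless recovery factor.
#' @examples
#' cal <- calibration(28.9)
#' recovery_factor(4.335, 0.3, cal)     # 0.5
#' @export
recovery_factor <- function(count_rate, known_activity, calibration) {
  stopifnot(inherits(calibration, "calibration"))
  if (any(!is.finite(known_activity)) || any(known_activity <= 0))
    stop("'known_activity' must be > 0 MBq")
  count_rate / (calibration$sensitivity * known_activity)
}

# logistic recovery curve: R(v) = 1 - 1/(1 + (v/b1)^b2)
logistic_recovery <- function(v, b1, b2) {
  w <- (v / b1)^b2
  w / (1 + w)
}

#' Fit the two-parameter logistic recovery curve
#'
#' Fits \deqn{R(v) = 1 - \frac{1}{1 + (v/b_1)^{b_2}}} to per-insert
#' recovery observations by nonlinear least squares.  \eqn{b_1} (ml) is the
#' volume at which half the counts are recovered — \eqn{R(b_1) = 0.5} for
#' any \eqn{b_2} — and \eqn{b_2} controls the steepness.  Positivity of
#' both parameters is enforced by fitting on the log scale; the reported
#' parameter covariance is transformed back to the \eqn{(b_1, b_2)} scale
#' by the delta method.
#'
#' Starting values: \eqn{b_1} at the observed volume whose recovery is
#' nearest 0.5, \eqn{b_2 = 1}.
#'
#' @param observations data frame with columns `volume` (ml), `count_rate`
#'   (cps) and `activity` (MBq, known insert activity) — or pre-computed
#'   `recovery` instead of `count_rate`/`activity`.
#' @param calibration a [calibration] object (needed when recoveries are
#'   derived from count rates).
#' @return Object of class `recovery_curve`: list with `b1`, `b2`,
#'   `covariance` (2x2, on the (b1, b2) scale), `observations`, `fitted`,
#'   `residuals` and the underlying `nls` fit.
#' @examples
#' v <- c(0.5, 1, 2, 5, 10, 50, 100)
#' obs <- data.frame(volume = v, recovery = 1 - 1 / (1 + (v / 5)^1.5))
#' fit_recovery_curve(obs)
#' @export
fit_recovery_curve <- function(observations, calibration = NULL) {
  if (!is.data.frame(observations)) stop("'observations' must be a data frame")
  if (!"recovery" %in% names(observations)) {
    if (is.null(calibration))
      stop("a 'calibration' is required to derive recoveries from count rates")
    if (!all(c("volume", "count_rate", "activity") %in% names(observations)))
      stop("need columns volume, count_rate, activity (or volume, recovery)")
    observations$recovery <- recovery_factor(observations$count_rate,
                                             observations$activity, calibration)
  }
  v <- observations$volume; R <- observations$recovery
  if (length(unique(v)) < 3L)
    stop("at least 3 observations at distinct volumes are required")
  if (any(v <= 0)) stop("insert volumes must be > 0 ml")

  b1_start <- v[which.min(abs(R - 0.5))]
  fit <- minpack.lm::nlsLM(
    recovery ~ 1 - 1 / (1 + (volume / exp(lb1))^exp(lb2)),
    data = data.frame(volume = v, recovery = R),
    start = list(lb1 = log(b1_start), lb2 = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!fit$convInfo$isConv)
    stop("recovery-curve fit did not converge: ", fit$convInfo$stopMessage)
  theta <- stats::coef(fit)
  b1 <- exp(theta[["lb1"]]); b2 <- exp(theta[["lb2"]])
  # delta method back to (b1, b2): J = diag(b1, b2)
  vc_log <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  J <- diag(c(b1, b2))
  covariance <- J %*% vc_log %*% J
  dimnames(covariance) <- list(c("b1", "b2"), c("b1", "b2"))

  fitted <- logistic_recovery(v, b1, b2)
  structure(
    list(b1 = b1, b2 = b2, covariance = covariance,
         observations = observations, fitted = fitted,
         residuals = R - fitted, nls = fit),
    class = "recovery_curve"
  )
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat("Logistic recovery curve R(v) = 1 - 1/(1 + (v/b1)^b2)\n")
  cat(sprintf("  b1 = %.4g ml (half-recovery volume), b2 = %.4g\n", x$b1, x$b2))
  cat(sprintf("  fitted on %d insert observations, residual SD %.3g\n",
              nrow(x$observations), stats::sd(x$residuals)))
  invisible(x)
}

#' @export
coef.recovery_curve <- function(object, ...) c(b1 = object$b1, b2 = object$b2)

#' @export
residuals.recovery_curve <- function(object, ...) object$residuals

#' Evaluate the recovery curve with uncertainty
#'
#' \eqn{R(v)} at a delineated volume, with standard uncertainty combining
#' (in quadrature, first order) the parameter-covariance contribution and
#' the volume-uncertainty contribution \eqn{|\partial R/\partial v|\,u(v)}.
#' The volume uncertainty of the delineation is a user input.
#'
#' @param curve a [fit_recovery_curve()] result.
#' @param volume delineated volume in ml (> 0).
#' @param u_volume standard uncertainty of the volume (ml).
#' @return data frame with columns `volume`, `recovery`, `u_recovery`.
#' @export
recovery_at <- function(curve, volume, u_volume = 0) {
  stopifnot(inherits(curve, "recovery_curve"))
  volume <- as.numeric(volume)
  if (any(!is.finite(volume)) || any(volume <= 0)) stop("'volume' must be > 0 ml")
  b1 <- curve$b1; b2 <- curve$b2
  w <- (volume / b1)^b2
  R <- w / (1 + w)
  dRdw <- 1 / (1 + w)^2
  dRdv  <- dRdw * b2 * w / volume
  dRdb1 <- -dRdw * b2 * w / b1
  dRdb2 <- dRdw * w * log(volume / b1)
  vc <- curve$covariance
  var_par <- dRdb1^2 * vc[1, 1] + dRdb2^2 * vc[2, 2] + 2 * dRdb1 * dRdb2 * vc[1, 2]
  u <- sqrt(pmax(var_par, 0) + (dRdv * u_volume)^2)
  data.frame(volume = volume, recovery = R, u_recovery = u)
}

#' @rdname recovery_at
#' @param object a `recovery_curve`.
#' @param ... unused.
#' @export
predict.recovery_curve <- function(object, volume, u_volume = 0, ...) {
  recovery_at(object, volume, u_volume)
}

#' @export
plot.recovery_curve <- function(x, ...) {
  v <- x$observations$volume
  grid <- exp(seq(log(min(v) / 2), log(max(v) * 2), length.out = 200))
  pr <- recovery_at(x, grid, u_volume = 0)
  plot(v, x$observations$recovery, log = "x", ylim = c(0, 1.05),
       xlab = "volume (ml)", ylab = "recovery coefficient", pch = 19, ...)
  lines(grid, pr$recovery)
  lines(grid, pmin(1, pr$recovery + 1.96 * pr$u_recovery), lty = 2)
  lines(grid, pmax(0, pr$recovery - 1.96 * pr$u_recovery), lty = 2)
  invisible(x)
}

#' Quantify with the recovery-coefficient method
#'
#' Comparator method: counts inside an anatomical VOI (delineated on CT and
#' transferred to the emission image) are corrected for partial-volume
#' spill-out by the recovery coefficient at the delineated volume:
#' \eqn{A = C / (Q R(v))}.  Relative uncertainty combines u(C)/C, u(Q)/Q
#' and u(R)/R in quadrature; at small volumes the steep recovery curve
#' makes u(R)/R dominant.
#'
#' @param count_rate counts inside the anatomical VOI (cps).
#' @param u_count_rate its standard uncertainty (cps).
#' @param calibration a [calibration] object.
#' @param curve a fitted recovery curve from [fit_recovery_curve()].
#' @param volume delineated volume (ml).
#' @param u_volume standard uncertainty of the volume (ml).
#' @return An [activity_estimate] with method `"recovery_coefficient"`.
#' @export
quantify_rc <- function(count_rate, u_count_rate = 0, calibration, curve,
                        volume, u_volume = 0) {
  r <- recovery_at(curve, volume, u_volume)
  if (r$recovery <= 0) stop("recovery coefficient is not positive at this volume")
  activity_from_counts(count_rate, u_count_rate, calibration,
                       recovery = min(r$recovery, 1),
                       u_recovery = r$u_recovery,
                       method = "recovery_coefficient")
}
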