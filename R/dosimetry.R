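#' Fit a mono-exponential time-activity curve
#'
#' Fits \eqn{A(t) = A_0 e^{-\lambda t}} to serial activity measurements by
#' least squares on log-activity versus time (default: unweighted).  The
#' time-integrated activity is the analytic integral from zero to
#' infinity, \eqn{TIA = A_0 / \lambda}, i.e. the total number of decays in
#' MBq·h; the effective half-life is \eqn{\ln 2 / \lambda}, combining
#' physical decay and biological clearance.
#'
#' With `weighting = "relative"`, points are weighted by
#' \eqn{(A/u(A))^2} — the inverse variance on the log scale, since
#' \eqn{u(\ln A) = u(A)/A}.
#'
#' The uncertainty of the TIA follows from the delta method on
#' \eqn{TIA = e^{\ln A_0}/\lambda} with the full \eqn{(\ln A_0, \lambda)}
#' covariance:
#' \deqn{u^2(TIA) = TIA^2\left[u^2(\ln A_0) + (u(\lambda)/\lambda)^2
#'       - 2\,\mathrm{cov}(\ln A_0, \lambda)/\lambda\right].}
#'
#' @param time sample times in hours post-injection.
#' @param activity activities in MBq (> 0).
#' @param u_activity standard uncertainties in MBq (used only for
#'   `weighting = "relative"` and carried in the returned object).
#' @param weighting `"none"` (default) or `"relative"`.
#' @param data optionally, a data frame with columns `time_h`,
#'   `activity_MBq` and (optionally) `u_activity_MBq`, as read by
#'   [read_tac_csv()]; overrides the vector arguments.
#' @return Object of class `tac_fit`: list with `A0` (MBq), `lambda`
#'   (per hour), `half_life_h`, `tia` (MBq·h), `u_tia` (MBq·h, `NA` with
#'   fewer than 3 points), `covariance` (2x2 of (ln A0, lambda)),
#'   `fitted`, `residuals` (log scale) and the inputs.
#' @examples
#' t <- c(43.0, 115.1, 163.7)
#' fit <- fit_monoexponential(t, c(7.88, 3.58, 2.02))
#' fit$tia        # ~1143 MBq.h
#' @export
fit_monoexponential <- function(time, activity, u_activity = NULL,
                                weighting = c("none", "relative"),
                                data = NULL) {
  if (!is.null(data)) {
    time <- data$time_h; activity <- data$activity_MBq
    u_activity <- data$u_activity_MBq
  }
  weighting <- match.arg(weighting)
  time <- as.numeric(time); activity <- as.numeric(activity)
  n <- length(time)
  if (n < 2L) stop("at least two time-activity samples are required")
  if (length(activity) != n) stop("'time' and 'activity' lengths differ")
  if (anyDuplicated(time)) stop("sample times must be distinct")
  if (any(!is.finite(activity)) || any(activity <= 0))
    stop("activities must be positive for the log-linear fit")
  if (any(time < 0)) stop("times must be >= 0")

  y <- log(activity)
  w <- if (weighting == "relative") {
    if (is.null(u_activity) || any(u_activity <= 0))
      stop("'relative' weighting requires positive u_activity")
    (activity / u_activity)^2
  } else rep(1, n)

  fit <- stats::lm(y ~ time, weights = w)
  lnA0 <- unname(stats::coef(fit)[1])
  lambda <- -unname(stats::coef(fit)[2])
  if (!is.finite(lambda) || lambda <= 0)
    stop("fitted decay constant is not positive; data do not decay")
  A0 <- exp(lnA0)
  tia <- A0 / lambda

  if (n >= 3L) {
    # (intercept, slope) = (lnA0, -lambda); suppress the "perfect fit"
    # warning summary.lm emits on noiseless data
    vc <- suppressWarnings(stats::vcov(fit))
    covariance <- matrix(c(vc[1, 1], -vc[1, 2], -vc[2, 1], vc[2, 2]), 2, 2,
                         dimnames = list(c("lnA0", "lambda"), c("lnA0", "lambda")))
    u_tia <- tia_uncertainty_(tia, lambda, covariance)
  } else {
    covariance <- matrix(NA_real_, 2, 2,
                         dimnames = list(c("lnA0", "lambda"), c("lnA0", "lambda")))
    u_tia <- NA_real_
  }

  structure(
    list(A0 = A0, lambda = lambda, half_life_h = log(2) / lambda,
         tia = tia, u_tia = u_tia, covariance = covariance,
         time = time, activity = activity, u_activity = u_activity,
         weighting = weighting,
         fitted = A0 * exp(-lambda * time),
         residuals = y - (lnA0 - lambda * time)),
    class = "tac_fit"
  )
}

tia_uncertainty_ <- function(tia, lambda, covariance) {
  v <- covariance[1, 1] + covariance[2, 2] / lambda^2 -
    2 * covariance[1, 2] / lambda
  if (!is.finite(v)) return(NA_real_)
  tia * sqrt(max(v, 0))
}

#' Time-integrated-activity uncertainty by the delta method
#'
#' @param fit a [fit_monoexponential()] result.
#' @return u(TIA) in MBq·h.
#' @export
tia_uncertainty <- function(fit) {
  stopifnot(inherits(fit, "tac_fit"))
  if (any(!is.finite(fit$covariance)))
    stop("covariance unavailable (fewer than 3 samples)")
  tia_uncertainty_(fit$tia, fit$lambda, fit$covariance)
}

#' @export
print.tac_fit <- function(x, ...) {
  cat("Mono-exponential time-activity fit\n")
  cat(sprintf("  A0 = %.5g MBq, lambda = %.5g /h (T1/2,eff = %.4g h)\n",
              x$A0, x$lambda, x$half_life_h))
  if (is.na(x$u_tia))
    cat(sprintf("  TIA = %.5g MBq.h\n", x$tia))
  else
    cat(sprintf("  TIA = %.5g +/- %.2g MBq.h\n", x$tia, x$u_tia))
  invisible(x)
}

#' @export
summary.tac_fit <- function(object, ...) {
  print(object)
  tab <- cbind(time_h = object$time, activity_MBq = object$activity,
               fitted_MBq = object$fitted,
               log_residual = object$residuals)
  cat("\n"); print(round(tab, 4))
  invisible(object)
}

#' @export
coef.tac_fit <- function(object, ...) c(A0 = object$A0, lambda = object$lambda)

#' @export
residuals.tac_fit <- function(object, ...) object$residuals

#' @export
fitted.tac_fit <- function(object, ...) object$fitted

#' @export
predict.tac_fit <- function(object, time = object$time, ...) {
  object$A0 * exp(-object$lambda * as.numeric(time))
}

#' @export
plot.tac_fit <- function(x, ...) {
  tt <- seq(0, max(x$time) * 1.1, length.out = 100)
  plot(x$time, x$activity, xlab = "time post-injection (h)",
       ylab = "activity (MBq)", pch = 19,
       ylim = range(0, x$activity, x$A0), xlim = c(0, max(tt)), ...)
  lines(tt, predict(x, tt))
  if (!is.null(x$u_activity))
    arrows(x$time, x$activity - x$u_activity, x$time, x$activity + x$u_activity,
           angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Simulate draws from a fitted time-activity model
#'
#' Generates replicate activity series at the fitted time points with
#' lognormal measurement noise, for parametric-bootstrap checks of the
#' fitting chain.
#'
#' @param object a `tac_fit`.
#' @param nsim number of replicate series.
#' @param seed integer seed.
#' @param cv relative measurement noise (lognormal sdlog), default 0.02.
#' @param ... unused.
#' @return A matrix, one column per replicate.
#' @export
simulate.tac_fit <- function(object, nsim = 1, seed = NULL, cv = 0.02, ...) {
  mu <- log(predict(object))
  with_seed(seed, {
    matrix(stats::rlnorm(length(mu) * nsim, meanlog = mu, sdlog = cv),
           nrow = length(mu))
  })
}

#' Absorbed dose from time-integrated activity
#'
#' The self-dose form of the MIRD equation: \eqn{D = TIA \times S} with
#' dose factor \eqn{S} in Gy per MBq·h for the source/target geometry
#' (contributions from activity outside the lesion are neglected).
#' Relative dose uncertainty combines u(TIA)/TIA and u(S)/S in quadrature.
#'
#' @param fit a [fit_monoexponential()] result.
#' @param dose_factor S in Gy/(MBq·h) (> 0).
#' @param u_dose_factor standard uncertainty of S.
#' @param mass sphere/lesion mass in g (metadata, optional).
#' @return Object of class `dose_result`: list with `dose` (Gy), `u_dose`,
#'   `tia`, `u_tia`, `dose_factor`, `mass`.
#' @export
absorbed_dose <- function(fit, dose_factor, u_dose_factor = 0, mass = NA_real_) {
  stopifnot(inherits(fit, "tac_fit"))
  if (!is.finite(dose_factor) || dose_factor <= 0)
    stop("'dose_factor' must be > 0 Gy/(MBq.h)")
  D <- fit$tia * dose_factor
  rel2 <- (u_dose_factor / dose_factor)^2
  if (!is.na(fit$u_tia)) rel2 <- rel2 + (fit$u_tia / fit$tia)^2
  structure(
    list(dose = D, u_dose = D * sqrt(rel2), tia = fit$tia, u_tia = fit$u_tia,
         dose_factor = dose_factor, u_dose_factor = u_dose_factor, mass = mass),
    class = "dose_result"
  )
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("absorbed dose: D = %.4g +/- %.2g Gy  (TIA %.5g MBq.h, S %.4g Gy/MBq.h)\n",
              x$dose, x$u_dose, x$tia, x$dose_factor))
  invisible(x)
}

#' Electron-local-deposition sphere dose factor
#'
#' A physics surrogate for tabulated unit-density-sphere self-dose factors:
#' assumes the mean electron (beta + conversion/Auger) energy per decay is
#' deposited locally within the sphere, giving
#' \deqn{S = \frac{E_e \cdot 1.602\times10^{-13}\,\mathrm{J/MeV}
#'       \cdot 3.6\times10^{9}\,\mathrm{decays/(MBq\,h)}}{m\,[\mathrm{kg}]}}
#' in Gy/(MBq·h).  Photon self-absorption is negligible for small spheres,
#' so this is a slight underestimate of the full factor; an optional
#' photon term `photon_energy * photon_absorbed_fraction` can be added.
#' User-supplied tabulated factors (see [dose_factor_from_table()]) take
#' precedence for production dosimetry.
#'
#' @param mass_g sphere mass in grams (> 0).
#' @param electron_energy_mev mean electron energy per decay in MeV
#'   (default 0.192, I-131).
#' @param photon_energy_mev mean photon energy per decay in MeV (used only
#'   with a non-zero absorbed fraction).
#' @param photon_absorbed_fraction fraction of photon energy absorbed in
#'   the sphere (default 0).
#' @return Dose factor in Gy/(MBq·h).
#' @examples
#' sphere_dose_factor(2.6)    # ~0.0426 Gy/(MBq.h) for I-131
#' @export
sphere_dose_factor <- function(mass_g, electron_energy_mev = 0.192,
                               photon_energy_mev = 0.382,
                               photon_absorbed_fraction = 0) {
  if (!is.finite(mass_g) || mass_g <= 0) stop("'mass_g' must be > 0")
  e <- electron_energy_mev + photon_energy_mev * photon_absorbed_fraction
  e * 1.602e-13 * 3.6e9 / (mass_g / 1000)
}

#' Interpolate a dose factor from a tabulated mass-factor curve
#'
#' Log-log linear interpolation in a user-supplied table of sphere masses
#' and dose factors (e.g. exported unit-density-sphere S values).
#'
#' @param table data frame with columns `mass_g` and `factor_Gy_per_MBqh`.
#' @param mass_g query mass in g; must lie within the table range.
#' @return Dose factor in Gy/(MBq·h).
#' @export
dose_factor_from_table <- function(table, mass_g) {
  stopifnot(all(c("mass_g", "factor_Gy_per_MBqh") %in% names(table)))
  if (any(table$mass_g <= 0) || any(table$factor_Gy_per_MBqh <= 0))
    stop("table masses and factors must be > 0")
  if (mass_g < min(table$mass_g) || mass_g > max(table$mass_g))
    stop("mass outside the tabulated range; extrapolation refused")
  o <- order(table$mass_g)
  exp(stats::approx(log(table$mass_g[o]), log(table$factor_Gy_per_MBqh[o]),
                    xout = log(mass_g))$y)
}
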