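#' Fit the concentric-VOI counts-versus-volume line
#'
#' Ordinary least squares of VOI count rate \eqn{C_i} on VOI volume
#' \eqn{v_i} over a concentric series.  The y-intercept \eqn{C_{v=0}}
#' estimates the count rate originating solely from the source: as the VOIs
#' grow, counts from surrounding activity accumulate linearly with volume
#' while the source contribution is constant (all of it already enclosed by
#' the innermost oversized VOI).  The gradient \eqn{a} (cps/ml) estimates
#' the average background count-rate concentration.
#'
#' The intercept and gradient are computed from the closed-form normal
#' equations
#' \deqn{C_{v=0} = \frac{\sum v_i^2 \sum C_i - \sum v_i \sum v_i C_i}
#'                      {n\sum v_i^2 - (\sum v_i)^2}}
#' and the intercept standard uncertainty from the residual scatter with
#' \eqn{n - 2} degrees of freedom:
#' \deqn{u^2(C_{v=0}) = \frac{\sum (C_i - a v_i - C_{v=0})^2}{n-2}
#'       \cdot \frac{\sum v_i^2}{n\sum v_i^2 - (\sum v_i)^2}.}
#'
#' A negative intercept is reported as-is with a warning flag; clamping to
#' zero would bias downstream coverage.
#'
#' @param series a [voi_series()] / [build_concentric_series()] result, or
#'   any data frame with `volume` and `count_rate` columns.
#' @param force logical; allow a two-point series for the intercept point
#'   estimate only (its uncertainty is undefined and returned as `NA`).
#' @return An object of class `voi_fit`: list with `intercept` (cps),
#'   `u_intercept` (cps), `gradient` (cps/ml), `fitted`, `residuals`, `n`,
#'   `series` and `warnings` (character vector of flags).
#' @examples
#' s <- voi_series(c(10, 20, 30, 40), c(610, 690, 820, 880))
#' f <- fit_intercept(s)
#' coef(f)                 # intercept 515 cps, gradient 9.4 cps/ml
#' f$u_intercept           # sqrt(615) ~= 24.8 cps
#' @export
fit_intercept <- function(series, force = FALSE) {
  if (!is.data.frame(series) || !all(c("volume", "count_rate") %in% names(series)))
    stop("'series' must have 'volume' and 'count_rate' columns")
  v <- as.numeric(series$volume)
  C <- as.numeric(series$count_rate)
  n <- length(v)
  if (anyDuplicated(v)) stop("duplicate VOI volumes: fit is degenerate")
  if (n < 2L) stop("at least two VOIs are required")
  if (n == 2L && !force)
    stop("n = 2: intercept uncertainty undefined (n - 2 = 0); use force = TRUE for the point estimate only")

  sv <- sum(v); svv <- sum(v^2); sC <- sum(C); svC <- sum(v * C)
  den <- n * svv - sv^2
  if (den <= 0) stop("degenerate design: volumes have no spread")
  intercept <- (svv * sC - sv * svC) / den
  gradient  <- (n * svC - sv * sC) / den
  fitted <- intercept + gradient * v
  res <- C - fitted

  warnings <- character(0)
  if (n >= 3L) {
    u2 <- sum(res^2) / (n - 2) * svv / den
    u_intercept <- sqrt(u2)
  } else {
    u_intercept <- NA_real_
    warnings <- c(warnings, "n=2: uncertainty unavailable")
  }
  if (intercept < 0)
    warnings <- c(warnings, "negative intercept")
  if (isTRUE(any(series$truncated)))
    warnings <- c(warnings, "VOI truncated by image boundary")

  structure(
    list(intercept = intercept, u_intercept = u_intercept,
         gradient = gradient, fitted = fitted, residuals = res,
         n = n, series = series, warnings = warnings),
    class = "voi_fit"
  )
}

#' @export
print.voi_fit <- function(x, ...) {
  cat("Concentric-VOI intercept fit\n")
  cat(sprintf("  n VOIs:     %d\n", x$n))
  cat(sprintf("  intercept:  %.6g cps  (u = %.3g cps)\n", x$intercept, x$u_intercept))
  cat(sprintf("  gradient:   %.6g cps/ml  (background concentration)\n", x$gradient))
  if (length(x$warnings)) cat("  warnings:  ", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.voi_fit <- function(object, ...) {
  cat("Concentric-VOI intercept fit (OLS of count rate on VOI volume)\n\n")
  tab <- cbind(volume_ml = object$series$volume,
               count_rate_cps = object$series$count_rate,
               fitted = object$fitted, residual = object$residuals)
  print(round(tab, 4))
  cat(sprintf("\nSource count rate (intercept): %.6g +/- %.4g cps\n",
              object$intercept, object$u_intercept))
  cat(sprintf("Background concentration (gradient): %.6g cps/ml\n", object$gradient))
  if (object$n > 2)
    cat(sprintf("Residual SD: %.4g cps on %d degrees of freedom\n",
                sqrt(sum(object$residuals^2) / (object$n - 2)), object$n - 2L))
  invisible(object)
}

#' @export
coef.voi_fit <- function(object, ...) {
  c(intercept = object$intercept, gradient = object$gradient)
}

#' @export
residuals.voi_fit <- function(object, ...) object$residuals

#' @export
fitted.voi_fit <- function(object, ...) object$fitted

#' @export
predict.voi_fit <- function(object, volume = object$series$volume, ...) {
  object$intercept + object$gradient * as.numeric(volume)
}

#' @export
plot.voi_fit <- function(x, ...) {
  v <- x$series$volume; C <- x$series$count_rate
  plot(v, C, xlim = c(0, max(v) * 1.05),
       ylim = range(0, C, x$intercept) * c(1, 1.05),
       xlab = "VOI volume (ml)", ylab = "VOI count rate (cps)",
       pch = 19, ...)
  abline(a = x$intercept, b = x$gradient, lty = 2)
  points(0, x$intercept, pch = 1, cex = 1.4)
  arrows(0, x$intercept - x$u_intercept, 0, x$intercept + x$u_intercept,
         angle = 90, code = 3, length = 0.04)
  invisible(x)
}
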