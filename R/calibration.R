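#' Least-squares strain-gauge calibration
#'
#' Fits the linear voltage-to-force law `F = a + b V` by the closed-form
#' normal-equation summations of ordinary least squares:
#' `b = (n S_xy - S_x S_y) / (n S_xx - S_x^2)` and
#' `a = (S_y - b S_x) / n`. Each of the rig's four gauges gets its own
#' independent fit.
#'
#' @param x calibration table: a data.frame with columns `voltage` and
#'   `force` (as written by [gen_gauge_data()]), or a numeric vector of
#'   voltages.
#' @param force forces in Newton when `x` is a voltage vector.
#' @return object of class `gauge_cal` with components `a` (intercept, N),
#'   `b` (slope, N/V), `n`, `residual_sd` (N), `r_squared`, `fitted`,
#'   `residuals` and the data.
#' @seealso [apply_calibration()], [calibration_error()]
#' @export
#' @examples
#' cal <- fit_linear(gen_gauge_data(0, 100, seq(0, 2, 0.5)))
#' coef(cal)
fit_linear <- function(x, force = NULL) {
  if (is.data.frame(x)) {
    v <- x$voltage; y <- x$force
    if (is.null(v) || is.null(y)) stop("need columns 'voltage' and 'force'")
  } else {
    v <- as.numeric(x); y <- as.numeric(force)
  }
  n <- length(v)
  if (n < 3L || length(y) != n) stop("need at least 3 (voltage, force) points")
  if (!all(is.finite(v)) || !all(is.finite(y))) stop("non-finite calibration data")
  Sx <- sum(v); Sy <- sum(y); Sxx <- sum(v^2); Sxy <- sum(v * y)
  den <- n * Sxx - Sx^2
  if (abs(den) <= 1e-12 * max(1, Sxx * n))
    stop("singular design: voltages are (nearly) all equal")
  b <- (n * Sxy - Sx * Sy) / den
  a <- (Sy - b * Sx) / n
  fitted <- a + b * v
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - Sy / n)^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else 1
  structure(list(a = a, b = b, n = n,
                 residual_sd = sqrt(rss / (n - 2L)),
                 r_squared = r2, fitted = fitted, residuals = res,
                 data = data.frame(voltage = v, force = y),
                 call = match.call()),
            class = "gauge_cal")
}

#' @export
print.gauge_cal <- function(x, ...) {
  cat("Strain-gauge calibration (least squares)\n")
  cat(sprintf("  force = %.6g + %.6g * voltage   [N; N/V]\n", x$a, x$b))
  cat(sprintf("  n = %d, residual SD = %.4g N, R^2 = %.6f\n",
              x$n, x$residual_sd, x$r_squared))
  invisible(x)
}

#' @export
coef.gauge_cal <- function(object, ...) c(a = object$a, b = object$b)

#' @export
residuals.gauge_cal <- function(object, ...) object$residuals

#' @export
predict.gauge_cal <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  v <- if (is.data.frame(newdata)) newdata$voltage else as.numeric(newdata)
  object$a + object$b * v
}

#' @export
summary.gauge_cal <- function(object, ...) {
  v <- object$data$voltage
  n <- object$n
  sxx <- sum((v - mean(v))^2)
  se_b <- object$residual_sd / sqrt(sxx)
  se_a <- object$residual_sd * sqrt(1 / n + mean(v)^2 / sxx)
  out <- list(coefficients = cbind(Estimate = c(a = object$a, b = object$b),
                                   `Std. Error` = c(se_a, se_b)),
              residual_sd = object$residual_sd, r_squared = object$r_squared,
              n = n)
  class(out) <- "summary.gauge_cal"
  out
}

#' @export
print.summary.gauge_cal <- function(x, ...) {
  cat("Strain-gauge calibration summary\n")
  print(x$coefficients)
  cat(sprintf("residual SD %.4g N on %d points, R^2 = %.6f\n",
              x$residual_sd, x$n, x$r_squared))
  invisible(x)
}

#' @export
plot.gauge_cal <- function(x, ...) {
  graphics::plot(x$data$voltage, x$data$force, xlab = "voltage [V]",
                 ylab = "force [N]", main = "Gauge calibration", ...)
  graphics::abline(x$a, x$b, col = "red3")
  invisible(x)
}

#' Convert a gauge voltage to force
#'
#' @param fit `gauge_cal` object.
#' @param voltage voltages in volt.
#' @return forces `a + b * voltage` in Newton.
#' @export
apply_calibration <- function(fit, voltage) {
  stopifnot(inherits(fit, "gauge_cal"))
  fit$a + fit$b * voltage
}

#' Audit a calibration against known true forces
#'
#' Maximum relative force error (percent) of the fitted calibration over a
#' truth table, excluding points whose true force magnitude falls below a
#' floor: a relative error bound is not meaningful as the force approaches
#' zero. The default floor is 5\% of the largest true force magnitude.
#'
#' @param fit `gauge_cal` object.
#' @param truth data.frame with columns `voltage` and `force` (true,
#'   noise-free forces).
#' @param floor_frac floor as a fraction of `max(abs(force))`.
#' @param floor_abs absolute floor in Newton, overriding `floor_frac` when
#'   larger.
#' @return maximum relative error in percent (scalar).
#' @export
calibration_error <- function(fit, truth, floor_frac = 0.05, floor_abs = 0) {
  stopifnot(inherits(fit, "gauge_cal"), is.data.frame(truth))
  f_true <- truth$force
  floor_N <- max(floor_frac * max(abs(f_true)), floor_abs)
  keep <- abs(f_true) >= floor_N & abs(f_true) > 0
  if (!any(keep))
    stop(errorCondition("all truth points below the force floor",
                        class = c("spinetrack_error_floor", "error", "condition")))
  pred <- apply_calibration(fit, truth$voltage[keep])
  max(abs(pred - f_true[keep]) / abs(f_true[keep])) * 100
}
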