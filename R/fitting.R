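#' Fit the 1/sqrt(t) approach of a D(t) curve
#'
#' The workhorse estimator of the package: ordinary least squares of
#' `D(t)` against `1/sqrt(t)` over `[t_min, t_max]`, whose intercept is
#' the long-time diffusivity `Dinf` and whose slope is the tail amplitude
#' `cD`. Parameter uncertainty is quantified by re-fitting over a sweep of
#' plausible lower time bounds `t0` (default 3..10 ms in 1 ms steps) and
#' reporting the standard deviation of the estimates across the sweep —
#' variability over modeling choices rather than within-fit statistical
#' error. When the curve carries per-point uncertainties,
#' `weights = "inverse_variance"` switches to weighted least squares.
#'
#' @param curve a `dt_curve` (cumulative kind), or a `sim_result` (its
#'   cumulative D(t) is used).
#' @param t_min lower bound of the central fit window (ms), default 10.
#' @param t_max upper bound (ms), default 500 (capped at the data range).
#' @param t0_grid lower-bound sweep for the uncertainty (ms), default
#'   `3:10`.
#' @param weights `"none"` (default) or `"inverse_variance"`.
#' @return An object of class `"dtfit"`: list with `Dinf`, `cD`,
#'   `Dinf_sd`, `cD_sd`, `fit_range`, `t0_grid`, `sweep` (per-t0
#'   estimates), `curve`, `n_points`.
#' @seealso [coef.dtfit()], [predict.dtfit()], [propagate_dt_uncertainty()]
#' @export
fit_dt <- function(curve, t_min = 10, t_max = 500, t0_grid = 3:10,
                   weights = c("none", "inverse_variance")) {
  if (inherits(curve, "sim_result")) curve <- as_dt_curve(curve)
  stopifnot(inherits(curve, "dt_curve"))
  weights <- match.arg(weights)
  t <- curve$t_ms; D <- curve$D_um2_per_ms
  t_max <- min(t_max, max(t))
  if (t_max <= max(t0_grid))
    stop("t_max must exceed the largest t0 in the sweep")
  w_all <- NULL
  if (weights == "inverse_variance") {
    if (is.null(curve$sd) || any(curve$sd <= 0))
      stop("inverse-variance weighting needs positive per-point sd")
    w_all <- 1 / curve$sd^2
  }
  ols <- function(lo) {
    sel <- t >= lo & t <= t_max
    if (sum(sel) < 6L)
      stop(sprintf("fewer than 6 points in the fit range [%g, %g] ms",
                   lo, t_max))
    x <- 1 / sqrt(t[sel])
    fit <- stats::lm.wfit(cbind(1, x), D[sel],
                          if (is.null(w_all)) rep(1, sum(sel))
                          else w_all[sel])
    fit$coefficients
  }
  central <- ols(t_min)
  sweep <- vapply(t0_grid, ols, numeric(2))
  Dinf <- unname(central[1L]); cD <- unname(central[2L])
  if (Dinf <= 0)
    warning("fitted Dinf is non-positive: the curve is not in the ",
            "long-time 1/sqrt(t) regime")
  structure(
    list(Dinf = Dinf, cD = cD,
         Dinf_sd = stats::sd(sweep[1L, ]), cD_sd = stats::sd(sweep[2L, ]),
         fit_range = c(t_min, t_max), t0_grid = t0_grid,
         sweep = t(sweep), curve = curve,
         n_points = sum(t >= t_min & t <= t_max)),
    class = "dtfit")
}

#' @export
print.dtfit <- function(x, ...) {
  cat("D(t) = Dinf + cD/sqrt(t) fit\n")
  cat(sprintf("  Dinf = %.5g +/- %.2g um^2/ms\n", x$Dinf, x$Dinf_sd))
  cat(sprintf("  cD   = %.5g +/- %.2g um^2 ms^-1/2\n", x$cD, x$cD_sd))
  cat(sprintf("  %d points in [%g, %g] ms; t0 sweep over [%g, %g] ms\n",
              x$n_points, x$fit_range[1L], x$fit_range[2L],
              min(x$t0_grid), max(x$t0_grid)))
  invisible(x)
}

#' @export
summary.dtfit <- function(object, D0 = 2, ...) {
  geo <- invert_to_geometry(min(object$Dinf, D0), max(object$cD, 0), D0 = D0)
  out <- list(fit = object, D0 = D0, tortuosity = geo$tortuosity,
              gamma0 = geo$gamma0)
  class(out) <- "summary.dtfit"
  out
}

#' @export
print.summary.dtfit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Implied geometry at D0 = %g um^2/ms (xi = 1):\n", x$D0))
  cat(sprintf("  <1/alpha> = %.5g   Gamma0 = %.5g um\n",
              x$tortuosity, x$gamma0))
  invisible(x)
}

#' @export
coef.dtfit <- function(object, ...) {
  c(Dinf = object$Dinf, cD = object$cD)
}

#' Predict D(t) (with propagated uncertainty) from a fit
#'
#' @param object a `dtfit`.
#' @param times times (ms); defaults to the fitted curve's grid.
#' @param se.fit also return the propagated `sigma_D(t)`.
#' @param ... unused.
#' @return Numeric vector of D values, or a list with `fit` and `se.fit`.
#' @export
predict.dtfit <- function(object, times = NULL, se.fit = FALSE, ...) {
  if (is.null(times)) times <- object$curve$t_ms
  if (any(times <= 0)) stop("times must be positive")
  val <- object$Dinf + object$cD / sqrt(times)
  if (!se.fit) return(val)
  list(fit = val, se.fit = propagate_dt_uncertainty(object, times))
}

#' @export
residuals.dtfit <- function(object, ...) {
  object$curve$D_um2_per_ms - predict(object, object$curve$t_ms)
}

#' @export
plot.dtfit <- function(x, ...) {
  t <- x$curve$t_ms
  graphics::plot(1 / sqrt(t), x$curve$D_um2_per_ms,
       xlab = expression(1 / sqrt(t)),
       ylab = expression(D(t) ~ (mu * m^2 / ms)),
       main = "D(t) vs 1/sqrt(t)", ...)
  graphics::abline(a = x$Dinf, b = x$cD, lty = 2)
  graphics::abline(v = 1 / sqrt(x$fit_range), col = "grey", lty = 3)
  invisible(x)
}

#' Propagated uncertainty of the fitted D(t) line
#'
#' Standard error propagation for the linear model in `1/sqrt(t)`:
#' `sigma_D(t) = sqrt(sigma_Dinf^2 + sigma_cD^2 / t)`.
#'
#' @param fit a `dtfit` (or any list with `Dinf_sd`, `cD_sd`).
#' @param t positive times (ms).
#' @return sigma_D(t) in um^2/ms.
#' @export
propagate_dt_uncertainty <- function(fit, t) {
  if (any(t <= 0)) stop("t must be positive")
  sqrt(fit$Dinf_sd^2 + fit$cD_sd^2 / t)
}
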