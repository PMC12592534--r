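#' Diffusion parameter set
#'
#' Bundles the dMRI-accessible parameters of the long-time expansion
#' `D(t) = Dinf + cD/sqrt(t)` with the geometric quantities they map to.
#' Units are fixed package-wide: um, ms, `D` in um^2/ms, `cD` in
#' um^2 ms^(-1/2), `gamma0` in um. When all fields are given, internal
#' consistency is enforced: `tortuosity = D0 / (xi^2 * Dinf)` and
#' `cD = 2 * gamma0 * sqrt(Dinf * xi^2 / pi) / xi^2`.
#'
#' @param D0 intrinsic (axoplasmic) diffusivity, um^2/ms; default 2.
#' @param Dinf long-time diffusivity asymptote, um^2/ms.
#' @param cD amplitude of the 1/sqrt(t) tail, um^2 ms^(-1/2).
#' @param xi sinuosity >= 1; default 1 (unknown skeleton).
#' @param tortuosity optional `<1/alpha>`; derived if missing.
#' @param gamma0 optional spectral plateau (um); derived if missing.
#' @return Object of class `"diffusion_params"`.
#' @export
diffusion_params <- function(D0 = 2, Dinf, cD, xi = 1,
                             tortuosity = NULL, gamma0 = NULL) {
  if (D0 <= 0 || Dinf <= 0) stop("D0 and Dinf must be positive")
  if (Dinf > D0 * (1 + 1e-12)) stop("Dinf must not exceed D0")
  if (cD < 0) stop("cD must be nonnegative")
  if (xi < 1) stop("sinuosity xi must be >= 1")
  tort_derived <- D0 / (xi^2 * Dinf)
  g0_derived <- cD * xi^2 / (2 * sqrt(Dinf * xi^2 / pi))
  if (is.null(tortuosity)) tortuosity <- tort_derived
  else if (abs(tortuosity - tort_derived) > 1e-10 * abs(tort_derived))
    stop("inconsistent fields: tortuosity != D0/(xi^2 * Dinf)")
  if (is.null(gamma0)) gamma0 <- g0_derived
  else if (abs(gamma0 - g0_derived) > 1e-10 * max(abs(g0_derived), 1e-300))
    stop("inconsistent fields: gamma0 != cD * xi^2 / (2 sqrt(Dinf xi^2/pi))")
  structure(list(D0 = D0, Dinf = Dinf, cD = cD, xi = xi,
                 tortuosity = tortuosity, gamma0 = gamma0),
            class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf("Diffusion parameters (D0 = %.4g um^2/ms, xi = %.4g):\n",
              x$D0, x$xi))
  cat(sprintf("  Dinf = %.5g um^2/ms   cD = %.5g um^2 ms^-1/2\n",
              x$Dinf, x$cD))
  cat(sprintf("  <1/alpha> = %.5g      Gamma0 = %.5g um\n",
              x$tortuosity, x$gamma0))
  invisible(x)
}

#' A sampled D(t) curve
#'
#' @param t_ms positive ascending times (ms).
#' @param D_um2_per_ms positive diffusivities (um^2/ms).
#' @param sd optional per-point uncertainty.
#' @param kind `"cumulative"` (D = MSD/2t, the pulsed-gradient observable)
#'   or `"instantaneous"` (d MSD / 2 dt).
#' @return Object of class `"dt_curve"`.
#' @export
dt_curve <- function(t_ms, D_um2_per_ms, sd = NULL, kind = "cumulative") {
  t_ms <- as.numeric(t_ms); D_um2_per_ms <- as.numeric(D_um2_per_ms)
  if (length(t_ms) != length(D_um2_per_ms))
    stop("times and values must have equal length")
  if (any(t_ms <= 0)) stop("times must be positive")
  if (any(diff(t_ms) <= 0)) stop("times must be strictly ascending")
  if (any(D_um2_per_ms <= 0)) stop("diffusivities must be positive")
  kind <- match.arg(kind, c("cumulative", "instantaneous"))
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    if (length(sd) != length(t_ms) || any(sd < 0))
      stop("sd must be nonnegative and match the time grid")
  }
  structure(list(t_ms = t_ms, D_um2_per_ms = D_um2_per_ms, sd = sd,
                 kind = kind), class = "dt_curve")
}

#' @export
print.dt_curve <- function(x, ...) {
  cat(sprintf("%s D(t): %d points, t in [%.4g, %.4g] ms, D in [%.4g, %.4g] um^2/ms\n",
              x$kind, length(x$t_ms), min(x$t_ms), max(x$t_ms),
              min(x$D_um2_per_ms), max(x$D_um2_per_ms)))
  invisible(x)
}

#' Predicted long-time diffusivity from geometry
#'
#' Tortuosity limit `Dinf = D0 / (<1/alpha> * xi^2)`: the reciprocal
#' relative cross-section averaged along the arc length sets the dc
#' attenuation of the diffusion coefficient (resistors in series), and
#' skeleton undulations rescale the whole of D(t) by `1/xi^2`.
#'
#' @param rel a `relative_profile` (or `axon_profile`).
#' @param D0 intrinsic diffusivity, um^2/ms; default 2.
#' @param xi sinuosity, default 1.
#' @return Dinf in um^2/ms.
#' @export
predict_dinf <- function(rel, D0 = 2, xi = 1) {
  if (D0 <= 0) stop("D0 must be positive")
  if (xi < 1) stop("xi must be >= 1")
  D0 / (tortuosity(rel) * xi^2)
}

#' Predicted tail amplitude from the spectral plateau
#'
#' `cD = 2 * gamma0 * sqrt(Dinf_l / pi) / xi^2`, where `Dinf_l` is the
#' long-time diffusivity of the stretched (arc-length) tube before
#' sinuosity rescaling and `gamma0` the low-q plateau of the power
#' spectral density of `log(alpha)`.
#'
#' @param gamma0 plateau (um), >= 0.
#' @param Dinf_l stretched-tube long-time diffusivity (um^2/ms), > 0.
#' @param xi sinuosity, default 1.
#' @return cD in um^2 ms^(-1/2).
#' @export
predict_cd <- function(gamma0, Dinf_l, xi = 1) {
  if (gamma0 < 0) stop("gamma0 must be nonnegative")
  if (Dinf_l <= 0) stop("Dinf_l must be positive")
  if (xi < 1) stop("xi must be >= 1")
  2 * gamma0 * sqrt(Dinf_l / pi) / xi^2
}

#' Asymptotic D(t) curve
#'
#' Evaluates `D(t) = Dinf + cD / sqrt(t)` (cumulative kind) on a time grid.
#'
#' @param params a `diffusion_params`.
#' @param times positive times (ms).
#' @return A `dt_curve`.
#' @export
dt_asymptote <- function(params, times) {
  stopifnot(inherits(params, "diffusion_params"))
  if (any(times <= 0)) stop("times must be positive")
  dt_curve(times, params$Dinf + params$cD / sqrt(times), kind = "cumulative")
}

#' Dispersive diffusivity
#'
#' Complex diffusivity `D(omega) = Dinf + (sqrt(pi)/2) cD sqrt(-i omega)`
#' with the branch `sqrt(-i) = (1 - i)/sqrt(2)` giving a real part above
#' Dinf (physical dispersion). The real part,
#' `Dinf + sqrt(pi/8) cD sqrt(omega)`, is the quantity accessed by
#' oscillating-gradient measurements.
#'
#' @param params a `diffusion_params`.
#' @param omega nonnegative angular frequencies (rad/ms).
#' @return List with `omega`, complex `D_complex`, and `D_real` (um^2/ms).
#' @export
dispersive_diffusivity <- function(params, omega) {
  stopifnot(inherits(params, "diffusion_params"))
  if (any(omega < 0)) stop("omega must be nonnegative")
  root <- sqrt(omega) * complex(real = 1 / sqrt(2), imaginary = -1 / sqrt(2))
  dc <- params$Dinf + (sqrt(pi) / 2) * params$cD * root
  list(omega = omega, D_complex = dc,
       D_real = params$Dinf + sqrt(pi / 8) * params$cD * sqrt(omega))
}

#' Long-time diffusivity corrections from an arbitrary spectrum
#'
#' Quadrature of the one-loop effective-medium result for the
#' instantaneous diffusion coefficient,
#' `delta_Dinst(t)/Dinf = Int dk/2pi Gamma_eta(k) (1 + 2 Dinf k^2 t) exp(-Dinf k^2 t)`
#' (integral over the full k line), together with the cumulative
#' correction `delta_D(t) = (1/t) Int_0^t delta_Dinst(t') dt'` evaluated
#' with the same kernel integrated in time analytically. For a flat
#' spectrum `Gamma = Gamma0` the long-t limits are
#' `Gamma0 sqrt(Dinf/(pi t))` (instantaneous) and twice that (cumulative).
#'
#' @param spectrum either a `spectral_density` (rectangle rule on its grid,
#'   extended symmetrically to -q; wavevectors beyond the sampled range
#'   contribute nothing) or a function `Gamma(k)` of nonnegative k
#'   returning um (adaptive quadrature on (0, k_max]).
#' @param Dinf long-time diffusivity (um^2/ms).
#' @param times positive times (ms).
#' @param k_max quadrature upper limit for callable spectra; default
#'   `Inf`. The cumulative kernel decays only as `3/(Dinf k^2 t)`, so a
#'   finite cutoff discards a slowly-converging tail; keep the default
#'   unless the spectrum itself is compactly supported.
#' @return List of two `dt_curve`s, `instantaneous` and `cumulative`,
#'   holding `Dinf + delta_D`.
#' @export
tail_from_spectrum <- function(spectrum, Dinf, times, k_max = NULL) {
  if (Dinf <= 0) stop("Dinf must be positive")
  if (any(times <= 0)) stop("times must be positive")
  times <- sort(times)
  inst_kern <- function(k, t) (1 + 2 * Dinf * k^2 * t) * exp(-Dinf * k^2 * t)
  # time-average of inst_kern over (0, t): (3 - (3 + 2bt) e^{-bt}) / (bt)
  cum_kern <- function(k, t) {
    bt <- Dinf * k^2 * t
    ifelse(bt < 1e-12, 1, (3 - (3 + 2 * bt) * exp(-bt)) / bt)
  }
  if (inherits(spectrum, "spectral_density")) {
    q <- spectrum$q; g <- spectrum$gamma
    dq <- c(diff(q)[1L], diff(q))
    di <- vapply(times, function(t)
      Dinf * sum(g * inst_kern(q, t) * dq) / pi, numeric(1))
    dc <- vapply(times, function(t)
      Dinf * sum(g * cum_kern(q, t) * dq) / pi, numeric(1))
  } else if (is.function(spectrum)) {
    g0 <- spectrum(0)
    if (!is.finite(g0) || g0 < 0)
      stop("spectrum must be finite and nonnegative at q -> 0 ",
           "(non-integrable low-q divergence rejected)")
    if (is.null(k_max)) k_max <- Inf
    di <- vapply(times, function(t)
      Dinf / pi * stats::integrate(function(k) spectrum(k) * inst_kern(k, t),
                                   0, k_max, rel.tol = 1e-8,
                                   subdivisions = 1000L)$value, numeric(1))
    dc <- vapply(times, function(t)
      Dinf / pi * stats::integrate(function(k) spectrum(k) * cum_kern(k, t),
                                   0, k_max, rel.tol = 1e-8,
                                   subdivisions = 1000L)$value, numeric(1))
  } else stop("spectrum must be a spectral_density or a function of k")
  list(instantaneous = dt_curve(times, Dinf + di, kind = "instantaneous"),
       cumulative = dt_curve(times, Dinf + dc, kind = "cumulative"))
}

#' Closed-form power-law tails for a structural universality class
#'
#' For low-wavevector spectra `Gamma_eta(q) ~ C |q|^p` the diffusive
#' metrics acquire power-law tails with dynamical exponent
#' `theta = (p + 1)/2`:
#' \itemize{
#'   \item `delta_Dinst(t)/Dinf = (1 + 2 theta) Gamma(theta) / (2 pi) * C / (Dinf t)^theta`
#'   \item `delta_Ddisp(omega)/Dinf = (1 + 2 theta) C / (2 sin(pi theta)) * (-i omega / Dinf)^theta`
#'   \item `delta_D(t)/Dinf = (1 + 2 theta) Gamma(theta) / (2 pi (1 - theta)) * C / (Dinf t)^theta`,
#'     valid only for theta < 1 (slower tails than the 1/t contributions it
#'     must dominate).
#' }
#' Short-range disorder is `p = 0`, `theta = 1/2`, reducing to
#' `cD = 2 Gamma0 sqrt(Dinf/pi)` with `C = Gamma0`.
#'
#' @param p structural exponent, > -1.
#' @param C amplitude, um^(1+p).
#' @param Dinf long-time diffusivity, um^2/ms.
#' @param t times (ms) for the time-domain tails; optional.
#' @param omega angular frequencies (rad/ms) for the dispersive tail;
#'   optional.
#' @param cumulative if `TRUE` (default) also return the cumulative-D(t)
#'   branch; rejected when theta >= 1.
#' @return List with `theta` and any of `delta_D_inst`, `delta_D_cum`
#'   (numeric, same length as `t`) and `delta_D_disp` (complex, same
#'   length as `omega`).
#' @export
powerlaw_tails <- function(p, C, Dinf, t = NULL, omega = NULL,
                           cumulative = TRUE) {
  if (p <= -1) stop("p must exceed -1 (integrability at q -> 0)")
  if (Dinf <= 0) stop("Dinf must be positive")
  theta <- (p + 1) / 2
  out <- list(theta = theta)
  if (!is.null(t)) {
    if (any(t <= 0)) stop("times must be positive")
    amp <- (1 + 2 * theta) * gamma(theta) / (2 * pi)
    out$delta_D_inst <- Dinf * amp * C / (Dinf * t)^theta
    if (cumulative) {
      if (theta >= 1)
        stop("cumulative D(t) tail requires theta < 1: for theta >= 1 the ",
             "1/t contributions dominate and conceal the structural tail")
      out$delta_D_cum <- out$delta_D_inst / (1 - theta)
    }
  }
  if (!is.null(omega)) {
    if (any(omega < 0)) stop("omega must be nonnegative")
    # (-i)^theta on the branch continuous from omega -> 0+
    phase <- complex(argument = -pi / 2 * theta)
    out$delta_D_disp <- Dinf * (1 + 2 * theta) * C / (2 * sin(pi * theta)) *
      (omega / Dinf)^theta * phase
  }
  out
}

#' Invert dMRI parameters to geometry
#'
#' The algebraic inverse of [predict_dinf()] and [predict_cd()]:
#' `<1/alpha> = D0 / (xi^2 * Dinf)` and
#' `Gamma0 = cD * xi / (2 sqrt(Dinf / pi))` (with `Dinf` the measured,
#' sinuosity-rescaled value, so the stretched-tube diffusivity is
#' `xi^2 * Dinf`). Round-trips with the forward maps to machine precision.
#'
#' @param Dinf_meas measured long-time diffusivity (um^2/ms), in (0, D0].
#' @param cD_meas measured tail amplitude, >= 0.
#' @param D0 intrinsic diffusivity, default 2 um^2/ms.
#' @param xi sinuosity, default 1.
#' @return List with `tortuosity` (<1/alpha>) and `gamma0` (um).
#' @export
invert_to_geometry <- function(Dinf_meas, cD_meas, D0 = 2, xi = 1) {
  if (any(Dinf_meas <= 0)) stop("Dinf must be positive")
  if (any(Dinf_meas > D0 * (1 + 1e-12)))
    stop("Dinf exceeds D0: implied tortuosity < 1 is unphysical")
  if (any(cD_meas < 0)) stop("cD must be nonnegative")
  if (xi < 1) stop("xi must be >= 1")
  Dinf_l <- Dinf_meas * xi^2
  list(tortuosity = D0 / (xi^2 * Dinf_meas),
       gamma0 = cD_meas * xi^2 / (2 * sqrt(Dinf_l / pi)))
}

#' Single-bead model plateau
#'
#' For identical multiplicative beads dropped at positions with
#' uncorrelated inter-bead intervals of mean `a_bar` and standard
#' deviation `sigma_a`, the low-q plateau of the log-area spectral density
#' is `Gamma0 = (sigma_a^2 / a_bar) * phi^2`, where the dimensionless bead
#' fraction `phi` is the integral of the single-bead log-profile divided
#' by `a_bar`. Regular placement (`sigma_a = 0`) kills the plateau;
#' stronger beads raise it quadratically.
#'
#' @param a_bar mean inter-bead spacing (um), > 0.
#' @param sigma_a spacing standard deviation (um), >= 0.
#' @param phi dimensionless bead fraction.
#' @return Gamma0 in um.
#' @export
bead_model_gamma0 <- function(a_bar, sigma_a, phi) {
  if (a_bar <= 0) stop("a_bar must be positive")
  if (sigma_a < 0) stop("sigma_a must be nonnegative")
  (sigma_a^2 / a_bar) * phi^2
}
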