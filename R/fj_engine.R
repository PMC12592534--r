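#' Finite-volume transition rates for Fick-Jacobs diffusion
#'
#' Discretizes `d/dt psi = D0 d/dx (A(x) d/dx psi/A(x))` on the profile's
#' uniform grid. The flux between neighboring sites uses an interface area
#' `A_tilde` (geometric mean of the two site areas by default, the natural
#' choice for multiplicative/log disorder; harmonic mean optional), giving
#' hop rates `k(j -> j+1) = D0 * A_tilde / (A_j * dl^2)`. The domain is
#' the even (mirrored) extension of the profile — a ring of period `2L`
#' whose seam interfaces join equal areas, so there is no geometric
#' discontinuity — and the stationary distribution is `pi_j` proportional
#' to `A_j` with detailed balance holding exactly.
#'
#' @param profile an `axon_profile`.
#' @param D0 intrinsic diffusivity (um^2/ms), default 2.
#' @param interface `"geometric"` (default) or `"harmonic"` interface
#'   area.
#' @return Object of class `"fj_generator"`: list with `areas` (mirrored,
#'   length `2N`), `k_right`, `k_left` (rates, 1/ms, ring-indexed), `dl`,
#'   `D0`, `n_sites`.
#' @export
build_generator <- function(profile, D0 = 2,
                            interface = c("geometric", "harmonic")) {
  stopifnot(inherits(profile, "axon_profile"))
  if (D0 <= 0) stop("D0 must be positive")
  interface <- match.arg(interface)
  A <- profile$area_um2
  if (any(A <= 0)) stop("all areas must be positive")
  dl <- profile$dl
  Aext <- c(A, rev(A))
  M <- length(Aext)
  Anext <- c(Aext[-1L], Aext[1L])
  Atil <- if (interface == "geometric") sqrt(Aext * Anext)
          else 2 * Aext * Anext / (Aext + Anext)
  # Atil[j] is the interface between ring sites j and j+1 (wrap M -> 1)
  k_right <- D0 * Atil / (Aext * dl^2)
  k_left <- D0 * c(Atil[M], Atil[-M]) / (Aext * dl^2)
  structure(list(areas = Aext, k_right = k_right, k_left = k_left,
                 dl = dl, D0 = D0, n_sites = M, interface = interface),
            class = "fj_generator")
}

#' Dense generator matrix (small systems)
#'
#' Master-equation matrix `K` with `dP/dt = K P` on the mirrored ring;
#' columns sum to zero (probability conservation). Intended for tests and
#' small instances.
#'
#' @param gen an `fj_generator`.
#' @return A dense `n_sites x n_sites` matrix.
#' @export
generator_matrix <- function(gen) {
  stopifnot(inherits(gen, "fj_generator"))
  M <- gen$n_sites
  if (M > 4000L) stop("dense matrix only supported up to 4000 sites")
  K <- matrix(0, M, M)
  right_to <- c(2:M, 1L)
  left_to <- c(M, 1:(M - 1L))
  for (j in seq_len(M)) {
    K[right_to[j], j] <- K[right_to[j], j] + gen$k_right[j]
    K[left_to[j], j] <- K[left_to[j], j] + gen$k_left[j]
    K[j, j] <- K[j, j] - gen$k_right[j] - gen$k_left[j]
  }
  K
}

#' Reference step length of a 3-D random-walk simulator
#'
#' Step length `sqrt(6 * D0 * dt)` of an isotropic 3-D Monte Carlo walker
#' with step duration `dt`. With the package defaults (`D0 = 2` um^2/ms,
#' `dt = 8.74e-5` ms, the step duration used as the documented reference
#' for realistic-microstructure simulations) this is 0.0324 um.
#'
#' @param D0 intrinsic diffusivity (um^2/ms), default 2.
#' @param dt step duration (ms), default 8.74e-5.
#' @return Step length in um.
#' @export
rw_step_length <- function(D0 = 2, dt = 8.74e-5) {
  if (D0 <= 0 || dt <= 0) stop("D0 and dt must be positive")
  sqrt(6 * D0 * dt)
}

sim_result <- function(times, msd, msd_se, n_walkers, seed, engine,
                       config = list()) {
  D_cum <- msd / (2 * times)
  D_se <- if (is.null(msd_se)) NULL else msd_se / (2 * times)
  # instantaneous D by central differences of MSD/2 on the time grid
  n <- length(times)
  D_inst <- numeric(n)
  if (n >= 3L) {
    D_inst[2:(n - 1)] <- (msd[3:n] - msd[1:(n - 2)]) /
      (2 * (times[3:n] - times[1:(n - 2)]))
    D_inst[1L] <- (msd[2L] - msd[1L]) / (2 * (times[2L] - times[1L]))
    D_inst[n] <- (msd[n] - msd[n - 1L]) / (2 * (times[n] - times[n - 1L]))
  } else D_inst[] <- D_cum
  structure(list(times = times, msd = msd, msd_se = msd_se,
                 D_cum = D_cum, D_se = D_se, D_inst = D_inst,
                 n_walkers = n_walkers, seed = seed, engine = engine,
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Fick-Jacobs %s simulation: %d report times, t in [%.4g, %.4g] ms\n",
              x$engine, length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  D(t): %.4g -> %.4g um^2/ms", x$D_cum[1L],
              x$D_cum[length(x$D_cum)]))
  if (!is.null(x$n_walkers) && !is.na(x$n_walkers))
    cat(sprintf("  (%d walkers, seed %d)", x$n_walkers, x$seed))
  cat("\n")
  invisible(x)
}

#' Convert a simulation result to a D(t) curve
#'
#' @param sim a `sim_result`.
#' @param kind `"cumulative"` or `"instantaneous"`.
#' @return A `dt_curve`.
#' @export
as_dt_curve <- function(sim, kind = c("cumulative", "instantaneous")) {
  stopifnot(inherits(sim, "sim_result"))
  kind <- match.arg(kind)
  if (kind == "cumulative")
    dt_curve(sim$times, sim$D_cum, sd = sim$D_se, kind = "cumulative")
  else {
    keep <- sim$D_inst > 0
    dt_curve(sim$times[keep], sim$D_inst[keep], kind = "instantaneous")
  }
}

#' Monte Carlo walkers in a Fick-Jacobs tube
#'
#' Discrete-time random walkers hop on the mirrored-ring lattice of
#' [build_generator()] with probabilities `rate * dt`. Initial positions
#' are drawn from the equilibrium distribution (proportional to the local
#' area, matching the spin density of water), and displacements are
#' unwrapped through the ring winding number, so the mean-squared
#' displacement grows without saturation. Reproducible given `seed`.
#'
#' @param profile an `axon_profile`.
#' @param D0 intrinsic diffusivity (um^2/ms), default 2.
#' @param n_walkers number of walkers, >= 100. Default 2e4.
#' @param t_max maximal diffusion time (ms). Default 500.
#' @param report_times times (ms) at which to report; default 64
#'   log-spaced points in `[1, t_max]`. Rounded to whole steps.
#' @param dt step duration (ms); default
#'   `0.2 * dl^2 / (D0 * max(A_tilde / A))`, keeping every hop
#'   probability at or below 0.2 per side. Rejected (with the maximal
#'   admissible value) if the total hop probability would exceed 0.5.
#' @param seed integer RNG seed.
#' @param interface interface-area rule, see [build_generator()].
#' @param equilibrium_start draw initial sites proportional to area
#'   (default TRUE); `FALSE` starts uniformly in x, which biases short-time
#'   D(t) on beaded profiles and exists for demonstrating that the
#'   equilibrium convention matters.
#' @return A `sim_result` (engine `"walker"`) with per-time standard
#'   errors.
#' @export
simulate_walkers <- function(profile, D0 = 2, n_walkers = 2e4, t_max = 500,
                             report_times = NULL, dt = NULL, seed = 1,
                             interface = "geometric",
                             equilibrium_start = TRUE) {
  gen <- build_generator(profile, D0 = D0, interface = interface)
  n_walkers <- as.integer(n_walkers)
  if (n_walkers < 100L) stop("need at least 100 walkers")
  if (is.null(report_times))
    report_times <- exp(seq(log(1), log(t_max), length.out = 64L))
  if (any(report_times <= 0) || max(report_times) > t_max)
    stop("report_times must lie in (0, t_max]")
  rate_tot <- gen$k_right + gen$k_left
  if (is.null(dt)) dt <- 0.2 / max(pmax(gen$k_right, gen$k_left))
  p_tot_max <- max(rate_tot) * dt
  if (p_tot_max > 0.5)
    stop(sprintf(
      "hop probability %.3g exceeds 0.5 at dt = %.3g ms; maximal admissible dt is %.3g ms",
      p_tot_max, dt, 0.5 / max(rate_tot)))
  steps <- sort(unique(pmax(1, round(report_times / dt))))
  times <- steps * dt
  set.seed(as.integer(seed))
  start <- sample.int(gen$n_sites, n_walkers, replace = TRUE,
                      prob = if (equilibrium_start) gen$areas else NULL)
  acc <- walk_ring(gen$k_left * dt, gen$k_right * dt, start,
                   as.integer(steps))
  msd <- acc[, 1L] / n_walkers * gen$dl^2
  v <- pmax(acc[, 2L] / n_walkers - (acc[, 1L] / n_walkers)^2, 0)
  msd_se <- sqrt(v / n_walkers) * gen$dl^2
  sim_result(times, msd, msd_se, n_walkers, as.integer(seed), "walker",
             config = list(D0 = D0, dt = dt, t_max = t_max,
                           interface = interface,
                           equilibrium_start = equilibrium_start,
                           n_sites = gen$n_sites, dl = gen$dl))
}

#' Exact spectral solution of the Fick-Jacobs master equation
#'
#' Deterministic oracle for small instances: the master-equation generator
#' on the mirrored ring is symmetrized with respect to its stationary
#' distribution and eigendecomposed, and the unwrapped mean-squared
#' displacement of an equilibrium-started walker follows in closed form
#' from the jump self-term plus the drift autocorrelation,
#' \deqn{MSD(t) = a_2 t - 2 \sum_m h_m^2
#'   \frac{e^{\lambda_m t} - 1 - \lambda_m t}{\lambda_m^2},}
#' where `a2 = dl^2 sum_j pi_j (k_j^+ + k_j^-)` is the bare jump
#' diffusivity, `h_m` the overlap of the local mean drift
#' `v_j = dl (k_j^+ - k_j^-)` with eigenmode m, and `lambda_m <= 0` the
#' relaxation rates. This is the same mirrored-ring dynamics the walker
#' engine samples, evaluated without Monte Carlo noise and with no
#' boundary artifact at any time. The enforced diffusion-length bound
#' (`sqrt(2 D0 t_max)` at most one eighth of the ring period) marks the
#' regime where the periodic tiling still represents an aperiodic axon.
#'
#' @param profile an `axon_profile`; at most ~8000 lattice sites after
#'   mirroring.
#' @param D0 intrinsic diffusivity (um^2/ms), default 2.
#' @param times report times (ms).
#' @param interface interface-area rule, see [build_generator()].
#' @return A `sim_result` (engine `"exact"`, no standard errors). The
#'   config records `D_eff`, the exact long-time diffusivity of the
#'   lattice model, `a2/2 + sum_m h_m^2 / lambda_m`.
#' @export
solve_msd_exact <- function(profile, D0 = 2, times, interface = "geometric") {
  gen <- build_generator(profile, D0 = D0, interface = interface)
  M <- gen$n_sites
  if (M > 8192L)
    stop(sprintf("mirrored lattice has %d sites; the exact solver supports at most 8192", M))
  times <- sort(as.numeric(times))
  if (any(times <= 0)) stop("times must be positive")
  period <- M * gen$dl
  t_lim <- (period / 8)^2 / (2 * D0)
  if (max(times) > t_lim)
    stop(sprintf(
      "requested t = %.4g ms exceeds the diffusion-length bound %.4g ms for a %.4g um ring period",
      max(times), t_lim, period))
  kp <- gen$k_right; km <- gen$k_left
  pi_st <- gen$areas / sum(gen$areas)
  # pi-symmetrized ring generator (symmetric; corner entries close the ring)
  S <- matrix(0, M, M)
  idx <- seq_len(M - 1L)
  off <- sqrt(kp[-M] * km[-1L])
  S[cbind(idx, idx + 1L)] <- off
  S[cbind(idx + 1L, idx)] <- off
  wrap <- sqrt(kp[M] * km[1L])
  S[1L, M] <- S[1L, M] + wrap
  S[M, 1L] <- S[M, 1L] + wrap
  diag(S) <- -(kp + km)
  eig <- eigen(S, symmetric = TRUE)
  lam <- pmin(eig$values, 0)
  v <- gen$dl * (kp - km)
  h2 <- drop(crossprod(eig$vectors, sqrt(pi_st) * v))^2
  a2 <- gen$dl^2 * sum(pi_st * (kp + km))
  msd <- vapply(times, function(t) {
    f <- ifelse(lam * t > -1e-8, t^2 / 2,
                (expm1(lam * t) - lam * t) / lam^2)
    a2 * t - 2 * sum(h2 * f)
  }, numeric(1))
  D_eff <- a2 / 2 + sum(h2[lam < 0] / lam[lam < 0])
  sim_result(times, msd, NULL, NA_integer_, NA_integer_, "exact",
             config = list(D0 = D0, interface = interface, n_sites = M,
                           dl = gen$dl, t_limit = t_lim, D_eff = D_eff))
}
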