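#' Generate a synthetic beaded-axon profile
#'
#' Randomly-placed-bead model of a varicose axon: bead centers are dropped
#' sequentially with inter-bead gaps drawn from a normal distribution
#' (mean `a_bar`, sd `sigma_a`, truncated below at `2*dl` to forbid
#' coincident beads), the resulting point density is convolved with a
#' unit-mass Gaussian kernel of width `sigma1`, scaled by the bead
#' amplitude `A1`, and added to the base area `A0`:
#' `A(x) = A0 + sum_m A1 * exp(-(x - x_m)^2 / (2 sigma1^2)) / sqrt(2 pi sigma1^2)`.
#' Beads are placed on an extended domain (`+/- 5 sigma1` beyond `[0, L]`)
#' and the profile cropped, so bead density is not diluted at the edges.
#'
#' Default parameter ranges are physiological for myelinated axons:
#' `A0 = pi * 0.5^2` um^2 (0.5 um radius), `A1` in [0.1, 2.5] um^2,
#' `sigma1` in [3, 7] um, `a_bar` in [3, 7] um, `sigma_a` in
#' [0.8, 1.2] * a_bar.
#'
#' The achieved gap sample moments (mean, sd after truncation) are
#' recorded in the `gap_stats` attribute; when `sigma_a` is comparable to
#' `a_bar` the truncation shifts them away from the nominal values, and
#' analyses based on interval statistics should use the achieved moments.
#'
#' @param A0 base area (um^2), > 0. Default `pi * 0.25`.
#' @param A1 bead amplitude (um^2), >= 0. Default 1.3.
#' @param sigma1 bead width (um), > 0. Default 5.
#' @param a_bar mean inter-bead spacing (um), > 0. Default 5.
#' @param sigma_a spacing sd (um), >= 0. Default `a_bar`.
#' @param L profile length (um), >= 10 * a_bar. Default 500.
#' @param dl grid spacing (um). Default 0.1.
#' @param seed integer RNG seed; same seed gives a bitwise-identical
#'   profile.
#' @param axon_id identifier.
#' @return An `axon_profile` with attributes `gap_stats` (list:
#'   `n_gaps`, `mean`, `sd`, `reject_fraction`) and `params` (the
#'   generating parameters).
#' @export
generate_bead_profile <- function(A0 = pi * 0.25, A1 = 1.3, sigma1 = 5,
                                  a_bar = 5, sigma_a = a_bar, L = 500,
                                  dl = 0.1, seed = 1,
                                  axon_id = sprintf("bead-%d", seed)) {
  if (A0 <= 0) stop("A0 must be positive")
  if (A1 < 0) stop("A1 must be nonnegative")
  if (sigma1 <= 0) stop("sigma1 must be positive")
  if (a_bar <= 0) stop("a_bar must be positive")
  if (sigma_a < 0) stop("sigma_a must be nonnegative")
  if (L < 10 * a_bar) stop("L must be at least 10 * a_bar")
  if (dl <= 0) stop("dl must be positive")
  set.seed(as.integer(seed))
  pad <- 5 * sigma1
  lo <- -pad; hi <- L + pad
  gap_min <- 2 * dl
  # sequential placement with truncated-normal gaps (rejection sampling)
  centers <- numeric(0)
  n_draw <- 0L; n_rej <- 0L
  # random phase so the process is stationary at x = lo
  x <- lo - stats::runif(1, 0, a_bar)
  repeat {
    repeat {
      g <- stats::rnorm(1, a_bar, sigma_a)
      n_draw <- n_draw + 1L
      if (g >= gap_min) break
      n_rej <- n_rej + 1L
    }
    x <- x + g
    if (x > hi) break
    centers <- c(centers, x)
  }
  rej_frac <- if (n_draw > 0L) n_rej / n_draw else 0
  if (rej_frac > 0.5)
    warning(sprintf(
      "gap truncation rejected %.0f%% of draws (sigma_a too large vs a_bar); proceeding with the truncated distribution",
      100 * rej_frac))
  grid <- seq(0, by = dl, length.out = floor(L / dl) + 1L)
  area <- rep(A0, length(grid))
  if (A1 > 0 && length(centers) > 0L) {
    norm <- A1 / sqrt(2 * pi * sigma1^2)
    win <- 6 * sigma1
    for (cm in centers) {
      j <- which(grid >= cm - win & grid <= cm + win)
      if (length(j))
        area[j] <- area[j] + norm * exp(-(grid[j] - cm)^2 / (2 * sigma1^2))
    }
  }
  gaps <- diff(centers)
  prof <- axon_profile(grid, area, axon_id = axon_id)
  attr(prof, "gap_stats") <- list(
    n_gaps = length(gaps),
    mean = if (length(gaps)) mean(gaps) else NA_real_,
    sd = if (length(gaps) > 1L) stats::sd(gaps) else NA_real_,
    reject_fraction = rej_frac)
  attr(prof, "params") <- list(A0 = A0, A1 = A1, sigma1 = sigma1,
                               a_bar = a_bar, sigma_a = sigma_a, L = L,
                               dl = dl, seed = as.integer(seed))
  prof
}

#' Generate a profile with a prescribed log-area spectrum
#'
#' Testing support for the structural universality classes: synthesizes a
#' Gaussian random field `eta` with one-sided target spectrum
#' `Gamma_eta(q) = C |q|^p exp(-(q * corr_length)^2)` by filtering complex
#' white noise in the Fourier domain, then exponentiates,
#' `A = Abar * exp(eta)`, so areas are positive by construction.
#'
#' @param p structural exponent, > -1 (low-q integrability).
#' @param C spectral amplitude, um^(1+p).
#' @param corr_length roll-off length (um), > 0. Default 1.
#' @param var_target optional variance of eta; when given, the spectrum is
#'   rescaled so the field variance matches it.
#' @param L record length (um). Default 500.
#' @param dl spacing (um). Default 0.1.
#' @param seed RNG seed.
#' @param mean_area Abar (um^2). Default `pi * 0.25`.
#' @param axon_id identifier.
#' @return An `axon_profile`.
#' @export
generate_spectrum_profile <- function(p, C, corr_length = 1,
                                      var_target = NULL, L = 500, dl = 0.1,
                                      seed = 1, mean_area = pi * 0.25,
                                      axon_id = sprintf("spec-%d", seed)) {
  if (p <= -1) stop("p must exceed -1 (integrability at q -> 0)")
  if (C < 0) stop("C must be nonnegative")
  if (corr_length <= 0) stop("corr_length must be positive")
  if (dl <= 0 || L <= 0) stop("L and dl must be positive")
  set.seed(as.integer(seed))
  n <- floor(L / dl) + 1L
  if (n < 16L) stop("fewer than 16 samples; increase L or decrease dl")
  Lrec <- n * dl
  k <- n %/% 2L
  q <- 2 * pi * seq_len(k) / Lrec
  shape <- q^p * exp(-(q * corr_length)^2)
  gam <- C * shape
  if (!is.null(var_target)) {
    v0 <- sum(gam) * (2 * pi / Lrec) / pi    # two-sided Parseval variance
    if (v0 <= 0) stop("target spectrum has zero variance")
    gam <- gam * var_target / v0
  }
  # Hermitian spectral synthesis: E|H_j|^2 = Gamma(q_j) * Lrec / dl^2
  amp <- sqrt(gam * Lrec) / dl
  H <- complex(real = stats::rnorm(k), imaginary = stats::rnorm(k)) / sqrt(2)
  H <- H * amp
  full <- complex(length.out = n)
  full[2L:(k + 1L)] <- H
  if (n %% 2L == 0L) {
    # even n: bin k is the self-conjugate Nyquist bin and must be real
    full[k + 1L] <- complex(real = sqrt(2) * Re(H[k]))
    if (k > 1L) full[n:(n - k + 2L)] <- Conj(full[2L:k])
  } else {
    full[n:(n - k + 1L)] <- Conj(full[2L:(k + 1L)])
  }
  eta <- Re(stats::fft(full, inverse = TRUE)) / n
  if (min(eta) < log(0.05))
    warning("field excursions drive min(alpha) below 0.05; ",
            "reduce C or var_target for a physiological profile")
  grid <- seq(0, by = dl, length.out = n)
  prof <- axon_profile(grid, mean_area * exp(eta), axon_id = axon_id)
  attr(prof, "params") <- list(p = p, C = C, corr_length = corr_length,
                               var_target = var_target, L = L, dl = dl,
                               seed = as.integer(seed),
                               mean_area = mean_area)
  prof
}
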