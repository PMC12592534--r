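# Shared fixture builders and independent oracles. Everything is built in
# code at test time; no stored data.

make_const_profile <- function(L = 50, dl = 0.1, A = pi * 0.25) {
  arc <- seq(0, by = dl, length.out = floor(L / dl) + 1L)
  axon_profile(arc, rep(A, length(arc)), axon_id = "const")
}

make_cosine_profile <- function(L = 100, dl = 0.1, eps = 0.6, lambda = 10,
                                Abar = 1) {
  arc <- seq(0, by = dl, length.out = floor(L / dl) + 1L)
  axon_profile(arc, Abar * (1 + eps * cos(2 * pi * arc / lambda)),
               axon_id = "cosine")
}

make_lognormal_profile <- function(n = 512, dl = 0.1, sd = 0.3, seed = 1) {
  set.seed(seed)
  arc <- seq(0, by = dl, length.out = n)
  axon_profile(arc, exp(rnorm(n, 0, sd)), axon_id = "lognormal")
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3)))
}

# Literal brute-force implementation of the nonparametric effect size:
# Hodges-Lehmann pseudo-median by explicit double loop, MAD about it,
# pooled with (n-1) weights. Deliberately naive and independent of the
# package's vectorized code path.
brute_force_deff <- function(x, y) {
  hl <- function(v) {
    n <- length(v)
    w <- c()
    for (i in 1:n) for (j in i:n) w <- c(w, (v[i] + v[j]) / 2)
    median(w)
  }
  madx <- median(abs(x - hl(x)))
  mady <- median(abs(y - hl(y)))
  nx <- length(x); ny <- length(y)
  pmad <- sqrt(((nx - 1) * madx^2 + (ny - 1) * mady^2) / (nx + ny - 2))
  (median(x) - median(y)) / pmad
}

# Brute-force unwrapped-MSD oracle for a small periodic lattice: build the
# master equation on many tiled periods with reflecting far ends, start at
# equilibrium within the central period, and evolve by eigendecomposition.
# Independent of the ring spectral formula used by solve_msd_exact.
brute_force_ring_msd <- function(areas, dl, D0, times, n_tiles = 31L) {
  M <- length(areas)
  Ae <- rep(areas, n_tiles)
  n <- length(Ae)
  Ati <- sqrt(Ae[-n] * Ae[-1L])
  kpe <- c(D0 * Ati / (Ae[-n] * dl^2), 0)
  kme <- c(0, D0 * Ati / (Ae[-1L] * dl^2))
  S <- matrix(0, n, n)
  off <- sqrt(kpe[-n] * kme[-1L])
  S[cbind(1:(n - 1), 2:n)] <- off
  S[cbind(2:n, 1:(n - 1))] <- off
  diag(S) <- -(kpe + kme)
  ee <- eigen(S, symmetric = TRUE)
  pie <- Ae / sum(Ae)
  x <- (0:(n - 1)) * dl
  ctr <- ((n_tiles %/% 2L) * M + 1L):((n_tiles %/% 2L + 1L) * M)
  w0 <- areas / sum(areas)
  vapply(times, function(t) {
    P <- ee$vectors %*% (exp(ee$values * t) * t(ee$vectors))
    msd <- 0
    for (k in seq_along(ctr)) {
      j0 <- ctr[k]
      pj <- P[, j0] * sqrt(pie / pie[j0])
      msd <- msd + w0[k] * sum(pj * (x - x[j0])^2)
    }
    msd
  }, numeric(1))
}

# Draw bead-generator parameters uniformly from the physiological ranges.
draw_bead_params <- function(seed) {
  set.seed(seed)
  a_bar <- runif(1, 3, 7)
  list(A1 = runif(1, 0.1, 2.5), sigma1 = runif(1, 3, 7), a_bar = a_bar,
       sigma_a = a_bar * runif(1, 0.8, 1.2))
}
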