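test_that("generator rates: constant tube, detailed balance, conservation", {
  pc <- make_const_profile(L = 5, dl = 0.1, A = 0.7)
  gen <- build_generator(pc, D0 = 2)
  expect_equal(unique(round(gen$k_right, 9)), 2 / 0.01)
  expect_equal(unique(round(gen$k_left, 9)), 2 / 0.01)

  pr <- make_lognormal_profile(n = 64, seed = 8)
  g <- build_generator(pr, D0 = 2)
  A <- g$areas; M <- g$n_sites
  nxt <- c(2:M, 1L)
  # detailed balance pi_j k(j->j+1) = pi_{j+1} k(j+1->j) around the ring
  expect_lt(max(abs(A * g$k_right - A[nxt] * g$k_left[nxt]) /
                (A * g$k_right)), 1e-12)
  K <- generator_matrix(g)
  expect_lt(max(abs(colSums(K))), 1e-9 * max(abs(K)))
})

test_that("interface rule sets the two-site rate ratio by detailed balance", {
  arc <- seq(0, by = 0.1, length.out = 20)
  p <- axon_profile(arc, rep(c(1, 4), 10))
  g <- build_generator(p, D0 = 2)
  # hop out of the small site is A_big/A_small times the reverse hop
  expect_equal(g$k_right[1] / g$k_left[2], 4, tolerance = 1e-12)
})

test_that("walkers reproduce free diffusion on a constant tube", {
  pc <- make_const_profile(L = 50, dl = 0.1, A = 0.785)
  sw <- simulate_walkers(pc, D0 = 2, n_walkers = 4000, t_max = 20,
                         report_times = c(1, 3, 8, 20), seed = 3)
  expect_true(all(abs(sw$D_cum - 2) < 3 * sw$D_se))
  expect_true(all(diff(sw$msd) > 0))
})

test_that("exact oracle matches a brute-force tiled master equation", {
  set.seed(10)
  arc <- seq(0, by = 0.25, length.out = 12)
  areas <- exp(rnorm(12, 0, 0.35))
  # build the same mirrored ring the engine uses, then brute-force it
  prof <- axon_profile(c(arc, max(arc) + 0.25 * (1:12)),
                       c(areas, rev(areas)))
  # the profile above has 24 sites; its mirrored ring has 48 (12 um
  # period), which bounds the admissible times
  tms <- c(0.02, 0.05, 0.1, 0.3)
  ex <- solve_msd_exact(prof, D0 = 2, times = tms)
  gen <- build_generator(prof, D0 = 2)
  bf <- brute_force_ring_msd(gen$areas, gen$dl, 2, tms, n_tiles = 9L)
  expect_equal(ex$msd, bf, tolerance = 1e-5)
})

test_that("exact oracle: free diffusion and the cosine tortuosity limit", {
  pc <- make_const_profile(L = 60, dl = 0.1, A = 0.5)
  ex <- solve_msd_exact(pc, D0 = 2, times = c(1, 5, 20, 50))
  expect_equal(ex$msd, 2 * 2 * c(1, 5, 20, 50), tolerance = 5e-3)

  pco <- make_cosine_profile(L = 150, dl = 0.1, eps = 0.6, lambda = 10)
  exc <- solve_msd_exact(pco, D0 = 2, times = c(50, 150, 300))
  target <- 2 * sqrt(1 - 0.36)
  # long-time slope settles on D0 sqrt(1 - eps^2)
  slope <- (exc$msd[3] - exc$msd[2]) / (2 * (300 - 150))
  expect_lt(abs(slope - target) / target, 0.01)
  expect_lt(abs(exc$config$D_eff - target) / target, 0.001)
})

test_that("walkers relax to the cosine tube tortuosity limit", {
  pco <- make_cosine_profile(L = 100, dl = 0.25, eps = 0.6, lambda = 10)
  sw <- simulate_walkers(pco, D0 = 2, n_walkers = 8000, t_max = 300,
                         report_times = c(150, 300), seed = 5)
  expect_lt(abs(sw$D_cum[2] - 1.6) / 1.6, 0.02)
})

test_that("walker and exact engines agree within Monte Carlo error", {
  tms <- c(2, 5, 10, 25, 40)
  for (s in 1:5) {
    par0 <- draw_bead_params(400 + s)
    prof <- generate_bead_profile(A1 = par0$A1, sigma1 = par0$sigma1,
                                  a_bar = par0$a_bar, sigma_a = par0$sigma_a,
                                  L = 80, dl = 0.1, seed = 500 + s)
    ex <- solve_msd_exact(prof, D0 = 2, times = tms)
    sw <- simulate_walkers(prof, D0 = 2, n_walkers = 5000, t_max = 40,
                           report_times = tms, seed = s)
    expect_true(all(abs(sw$D_cum - ex$D_cum) < 3 * sw$D_se),
                label = sprintf("profile %d within 3 SE", s))
  }
})

test_that("equilibrium initialization is required on beaded profiles", {
  # sharp, strong beads: a uniform-in-x start overweights the necks and
  # measurably inflates short-time D(t) relative to the spin-density
  # (area-proportional) start
  prof <- generate_bead_profile(A1 = 2.5, sigma1 = 1, a_bar = 3,
                                sigma_a = 2.4, L = 80, dl = 0.1, seed = 77)
  t1 <- c(0.5, 1, 2)
  eq <- simulate_walkers(prof, n_walkers = 3e4, t_max = 2,
                         report_times = t1, seed = 11)
  un <- simulate_walkers(prof, n_walkers = 3e4, t_max = 2,
                         report_times = t1, seed = 11,
                         equilibrium_start = FALSE)
  z <- abs(eq$D_cum - un$D_cum) / sqrt(eq$D_se^2 + un$D_se^2)
  expect_gt(max(z), 3)
})

test_that("reproducibility and rejection conditions", {
  prof <- generate_bead_profile(L = 60, dl = 0.1, seed = 2)
  s1 <- simulate_walkers(prof, n_walkers = 500, t_max = 5, seed = 9)
  s2 <- simulate_walkers(prof, n_walkers = 500, t_max = 5, seed = 9)
  expect_identical(s1$msd, s2$msd)

  expect_error(simulate_walkers(prof, n_walkers = 50, t_max = 5), "100")
  expect_error(simulate_walkers(prof, n_walkers = 500, t_max = 5,
                                dt = 1), "admissible")

  big <- generate_bead_profile(L = 600, dl = 0.1, seed = 2)
  expect_error(solve_msd_exact(big, times = 10), "8192")
  expect_error(solve_msd_exact(prof, times = 1e5), "diffusion-length")
})

test_that("the documented 3-D reference step length evaluates correctly", {
  expect_equal(rw_step_length(2, 8.74e-5), sqrt(6 * 2 * 8.74e-5))
  expect_equal(rw_step_length(1, 0.5), sqrt(3))
})
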