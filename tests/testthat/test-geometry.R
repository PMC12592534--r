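test_that("resampling a straight constant tube reproduces it exactly", {
  n <- 41
  pts <- cbind(seq(0, 40, length.out = n), 0, 0)
  prof <- resample_arclength(pts, rep(pi * 0.25, n), dl = 0.1)
  expect_length(prof$arc_um, 401L)
  expect_equal(prof$area_um2, rep(pi * 0.25, 401), tolerance = 1e-12)
  expect_equal(prof$dl, 0.1, tolerance = 1e-12)
})

test_that("chord-length arc coordinate recovers a known curve length", {
  R <- 12
  th <- seq(0, pi, length.out = 200)
  pts <- cbind(R * cos(th), R * sin(th), 0)
  prof <- resample_arclength(pts, rep(1, 200), dl = 0.05)
  # grid covers [0, floor(L/dl)*dl]; allow the sub-dl truncation on top of
  # the 0.1% chord-length tolerance
  expect_lt(pi * R - profile_length(prof), 0.05 + 1e-3 * pi * R)
  expect_lt(profile_length(prof) - pi * R, 1e-3 * pi * R)
})

test_that("spline interpolation of a linear area ramp is linear", {
  n <- 11
  pts <- cbind(seq(0, 10, length.out = n), 0, 0)
  areas <- seq(1, 2, length.out = n)
  prof <- resample_arclength(pts, areas, dl = 0.1)
  # dense linear-interpolation oracle at the midpoint
  oracle <- approx(seq(0, 10, length.out = n), areas, xout = 5)$y
  expect_equal(prof$area_um2[prof$arc_um == 5], oracle, tolerance = 1e-6)
})

test_that("resampling is idempotent on an already-uniform profile", {
  set.seed(3)
  n <- 201
  arc <- seq(0, 20, by = 0.1)
  pts <- cbind(arc, 0, 0)
  areas <- 1 + 0.3 * sin(arc) + 0.05 * rnorm(n)
  p1 <- resample_arclength(pts, areas, dl = 0.1)
  p2 <- resample_arclength(cbind(p1$arc_um, 0, 0), p1$area_um2, dl = 0.1)
  expect_lt(max(abs(p2$area_um2 - p1$area_um2) / p1$area_um2), 1e-6)
})

test_that("degenerate skeleton input is rejected", {
  pts <- cbind(c(0, 1, 1, 2, 3), 0, 0)
  expect_error(resample_arclength(pts, rep(1, 5), dl = 0.1),
               "duplicate")
  expect_error(resample_arclength(cbind(0:4, 0, 0), c(1, 1, -1, 1, 1)),
               "positive")
})

test_that("relative profile normalizes to unit mean alpha", {
  p <- make_const_profile(A = 0.7)
  rel <- relative_profile(p)
  expect_equal(rel$alpha, rep(1, length(p$arc_um)), tolerance = 1e-14)
  expect_equal(rel$eta, rep(0, length(p$arc_um)), tolerance = 1e-14)

  arc <- seq(0, by = 0.1, length.out = 20)
  p2 <- axon_profile(arc, rep(c(0.5, 1.5), 10))
  rel2 <- relative_profile(p2)
  expect_equal(rel2$mean_area, 1)
  expect_setequal(round(rel2$alpha, 12), c(0.5, 1.5))

  rel3 <- relative_profile(make_lognormal_profile(seed = 7))
  expect_lt(abs(mean(rel3$alpha) - 1), 1e-12)
  expect_equal(rel3$eta, log(rel3$alpha))
})

test_that("tortuosity matches closed forms and obeys Jensen's bound", {
  expect_equal(tortuosity(make_const_profile()), 1)

  arc <- seq(0, by = 0.1, length.out = 20)
  p <- axon_profile(arc, rep(c(0.5, 1.5), 10))
  expect_equal(tortuosity(p), 4 / 3, tolerance = 1e-12)

  # cosine tube: <1/(1 + eps cos)> = 1/sqrt(1 - eps^2), checked against a
  # dense quadrature oracle as well as the closed form
  p2 <- make_cosine_profile(L = 200, dl = 0.01, eps = 0.6, lambda = 10)
  quad <- integrate(function(x) 1 / (1 + 0.6 * cos(2 * pi * x / 10)),
                    0, 10, rel.tol = 1e-10)$value / 10
  expect_lt(abs(tortuosity(p2) - 1 / sqrt(1 - 0.36)) / 1.25, 5e-3)
  expect_lt(abs(tortuosity(p2) - quad) / quad, 5e-3)

  for (s in 1:5)
    expect_gte(tortuosity(make_lognormal_profile(seed = s)), 1)
})

test_that("small-fluctuation expansion: excess tortuosity is the variance", {
  for (s in 1:5) {
    set.seed(s)
    n <- 4096
    da <- 0.1 * (2 * runif(n) - 1)
    da <- da - mean(da)            # alpha averages to exactly 1
    alpha <- 1 + da
    arc <- seq(0, by = 0.1, length.out = n)
    tort <- tortuosity(axon_profile(arc, alpha))
    m2 <- mean(da^2); m3 <- mean(abs(da)^3)
    expect_lte(abs((tort - 1) - m2), 2 * m3)
  }
})

test_that("sinuosity matches arc-to-chord ratios and is rigid-motion invariant", {
  expect_equal(sinuosity(cbind(c(0, 5, 10), 0, 0)), 1, tolerance = 1e-12)

  th <- seq(0, pi, length.out = 400)
  half <- cbind(cos(th), sin(th), 0)
  expect_equal(sinuosity(half), pi / 2, tolerance = 1e-4)

  # small undulation y = b sin(kx): excess ~ (bk)^2/4, against a dense
  # numerical arc-length oracle
  b <- 0.2 / (2 * pi / 10); k <- 2 * pi / 10   # bk = 0.2
  x <- seq(0, 40, length.out = 4001)
  pts <- cbind(x, b * sin(k * x), 0)
  xi <- sinuosity(pts)
  oracle <- integrate(function(u) sqrt(1 + (b * k * cos(k * u))^2), 0, 40,
                      rel.tol = 1e-10)$value / 40
  expect_lt(abs(xi - oracle) / (oracle - 1), 0.02)
  expect_lt(abs((xi - 1) - 0.2^2 / 4) / (0.2^2 / 4), 0.10)

  Rm <- random_rotation(9)
  shift <- c(3, -2, 7)
  moved <- sweep(pts %*% t(Rm), 2, -shift)
  expect_equal(sinuosity(moved), xi, tolerance = 1e-10)

  expect_error(sinuosity(rbind(c(0, 0, 0), c(0, 0, 0))), "oincident")
})

test_that("volume weights are volume-proportional and normalized", {
  p1 <- make_const_profile(L = 10, A = 1)
  expect_equal(volume_weights(list(p1, p1)), c(0.5, 0.5))
  p3 <- make_const_profile(L = 30, A = 1)
  expect_equal(volume_weights(list(p1, p3)), c(0.25, 0.75),
               tolerance = 1e-12)
  set.seed(4)
  ps <- lapply(1:6, function(i) make_lognormal_profile(seed = i))
  expect_lt(abs(sum(volume_weights(ps)) - 1), 1e-12)
  expect_error(volume_weights(list()), "at least one")
})

test_that("thin_profile keeps the grid consistent and the statistics stable", {
  prof <- generate_bead_profile(L = 200, dl = 0.1, seed = 5)
  thin <- thin_profile(prof, 5L)
  expect_equal(thin$dl, 0.5, tolerance = 1e-9)
  expect_lt(abs(tortuosity(thin) - tortuosity(prof)), 1e-4)
})

test_that("profile invariants are enforced", {
  arc <- seq(0, by = 0.1, length.out = 20)
  expect_error(axon_profile(arc[1:10], rep(1, 10)), "16")
  expect_error(axon_profile(arc, rep(-1, 20)), "positive")
  expect_error(axon_profile(arc^1.01, rep(1, 20)), "uniform")
})
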