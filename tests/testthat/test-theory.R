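test_that("tortuosity limit prediction and sinuosity rescaling", {
  expect_equal(predict_dinf(make_const_profile(), D0 = 2, xi = 1), 2)
  arc <- seq(0, by = 0.1, length.out = 20)
  p <- axon_profile(arc, rep(c(0.5, 1.5), 10))
  expect_equal(predict_dinf(p, D0 = 2), 1.5, tolerance = 1e-12)
  expect_equal(predict_dinf(p, D0 = 2, xi = 1.02), 1.5 / 1.0404,
               tolerance = 1e-4)
})

test_that("tail amplitude from the spectral plateau", {
  expect_equal(predict_cd(0, 1.5), 0)
  expect_equal(predict_cd(0.1, 1.5), 0.2 * sqrt(1.5 / pi),
               tolerance = 1e-12)
  expect_equal(predict_cd(0.2, 1.5), 2 * predict_cd(0.1, 1.5))
})

test_that("asymptotic D(t) curve evaluates and decreases", {
  par0 <- diffusion_params(D0 = 2, Dinf = 1.5, cD = 0.138)
  cur <- dt_asymptote(par0, c(25, 100, 400))
  expect_equal(cur$D_um2_per_ms[2], 1.5 + 0.0138, tolerance = 1e-12)
  expect_true(all(diff(cur$D_um2_per_ms) < 0))
  par1 <- diffusion_params(D0 = 2, Dinf = 1.5, cD = 0)
  expect_equal(unique(dt_asymptote(par1, 1:10)$D_um2_per_ms), 1.5)
})

test_that("dispersive diffusivity branch gives the oscillating-gradient real part", {
  par0 <- diffusion_params(D0 = 2, Dinf = 1.5, cD = 0.138)
  d0 <- dispersive_diffusivity(par0, 0)
  expect_equal(d0$D_complex, complex(real = 1.5))
  dd <- dispersive_diffusivity(par0, c(0.01, 0.1, 1))
  expect_equal(Re(dd$D_complex), dd$D_real, tolerance = 1e-12)
  expect_true(all(Im(dd$D_complex) < 0))
  expect_equal(dd$D_real[3], 1.5 + sqrt(pi / 8) * 0.138, tolerance = 1e-3)
})

test_that("quadrature of the dispersion kernel matches flat-spectrum closed forms", {
  flat <- function(k) rep(0.05, length(k))
  tails <- tail_from_spectrum(flat, Dinf = 1.5, times = c(25, 100, 400))
  inst_expect <- 0.05 * sqrt(1.5 / (pi * c(25, 100, 400)))
  expect_equal(tails$instantaneous$D_um2_per_ms - 1.5, inst_expect,
               tolerance = 0.01)
  expect_equal(tails$cumulative$D_um2_per_ms - 1.5, 2 * inst_expect,
               tolerance = 0.01)

  zero <- tail_from_spectrum(function(k) rep(0, length(k)), 1.5, c(10, 100))
  expect_equal(zero$instantaneous$D_um2_per_ms, c(1.5, 1.5))

  # Lorentzian spectrum approaches the flat-spectrum law once the
  # diffusion length exceeds the correlation length
  lc <- 1
  lorentz <- function(k) 0.05 / (1 + (k * lc)^2)
  tl <- tail_from_spectrum(lorentz, Dinf = 1.5, times = 100)
  expect_lt(abs((tl$instantaneous$D_um2_per_ms - 1.5) /
                (0.05 * sqrt(1.5 / (pi * 100))) - 1), 0.05)
})

test_that("sampled spectra integrate consistently with callables", {
  q <- seq(2 * pi / 4000, 30, by = 2 * pi / 4000)
  sp <- structure(list(q = q, gamma = 0.05 / (1 + q^2),
                       record_length = 4000, dl = 0.1, n_segments = 1L),
                  class = "spectral_density")
  a <- tail_from_spectrum(sp, 1.5, times = c(20, 80))
  b <- tail_from_spectrum(function(k) 0.05 / (1 + k^2), 1.5,
                          times = c(20, 80))
  expect_equal(a$instantaneous$D_um2_per_ms, b$instantaneous$D_um2_per_ms,
               tolerance = 1e-3)
})

test_that("power-law tails reduce to the short-range closed forms at p = 0", {
  set.seed(21)
  for (i in 1:10) {
    g0 <- runif(1, 0.01, 0.4); Dinf <- runif(1, 0.5, 2); t <- runif(1, 20, 400)
    pw <- powerlaw_tails(p = 0, C = g0, Dinf = Dinf, t = t)
    expect_equal(pw$theta, 0.5)
    expect_equal(pw$delta_D_inst, g0 * sqrt(Dinf / (pi * t)),
                 tolerance = 1e-10)
    cd <- predict_cd(g0, Dinf)
    expect_equal(pw$delta_D_cum, cd / sqrt(t), tolerance = 1e-10)
  }
})

test_that("power-law tails match quadrature and handle the theta = 1 boundary", {
  flat <- function(k) rep(0.05, length(k))
  q <- tail_from_spectrum(flat, 1.5, times = 200)
  pw <- powerlaw_tails(p = 0, C = 0.05, Dinf = 1.5, t = 200)
  expect_equal(q$instantaneous$D_um2_per_ms - 1.5, pw$delta_D_inst,
               tolerance = 0.01)

  # p = 1 (theta = 1): cumulative branch invalid, instantaneous closed form
  expect_error(powerlaw_tails(p = 1, C = 0.1, Dinf = 1.5, t = 50),
               "theta < 1")
  pw1 <- powerlaw_tails(p = 1, C = 0.1, Dinf = 1.5, t = 50,
                        cumulative = FALSE)
  expect_equal(pw1$delta_D_inst, 1.5 * 3 / (2 * pi) * 0.1 / (1.5 * 50),
               tolerance = 1e-12)
  expect_error(powerlaw_tails(p = -1.2, C = 1, Dinf = 1), "integrability")
})

test_that("dispersive power-law tail agrees with the short-range branch form", {
  g0 <- 0.12; Dinf <- 1.4
  om <- c(0.05, 0.5)
  pw <- powerlaw_tails(p = 0, C = g0, Dinf = Dinf, omega = om)
  par0 <- diffusion_params(D0 = 2, Dinf = Dinf, cD = predict_cd(g0, Dinf))
  dd <- dispersive_diffusivity(par0, om)
  expect_equal(pw$delta_D_disp, dd$D_complex - Dinf, tolerance = 1e-12)
})

test_that("inverse map is the exact algebraic inverse of the forward maps", {
  geo <- invert_to_geometry(2, 0, D0 = 2)
  expect_equal(geo$tortuosity, 1)
  expect_equal(geo$gamma0, 0)

  geo2 <- invert_to_geometry(1.5, 0.2 * sqrt(1.5 / pi), D0 = 2)
  expect_equal(geo2$tortuosity, 4 / 3, tolerance = 1e-6)
  expect_equal(geo2$gamma0, 0.1, tolerance = 1e-6)

  set.seed(31)
  for (i in 1:100) {
    tort <- runif(1, 1, 3); g0 <- runif(1, 0, 0.5)
    xi <- runif(1, 1, 1.1); D0 <- runif(1, 1, 3)
    Dinf <- D0 / (tort * xi^2)
    cd <- predict_cd(g0, D0 / tort, xi = xi)
    back <- invert_to_geometry(Dinf, cd, D0 = D0, xi = xi)
    expect_equal(back$tortuosity, tort, tolerance = 1e-10)
    expect_equal(back$gamma0, g0, tolerance = 1e-10)
  }
  expect_error(invert_to_geometry(2.5, 0.1, D0 = 2), "unphysical")
})

test_that("diffusion_params enforces internal consistency", {
  p <- diffusion_params(D0 = 2, Dinf = 1.5, cD = 0.138, xi = 1.02)
  expect_equal(p$tortuosity, 2 / (1.02^2 * 1.5), tolerance = 1e-12)
  expect_equal(predict_cd(p$gamma0, p$Dinf * p$xi^2, xi = p$xi), p$cD,
               tolerance = 1e-12)
  expect_error(diffusion_params(D0 = 2, Dinf = 1.5, cD = 0.1,
                                tortuosity = 2), "inconsistent")
  expect_error(diffusion_params(D0 = 2, Dinf = 2.5, cD = 0.1), "exceed")
})

test_that("single-bead model plateau", {
  expect_equal(bead_model_gamma0(5, 0, 0.2), 0)
  expect_equal(bead_model_gamma0(5, 5, 0.113), 5 * 0.113^2,
               tolerance = 1e-12)
  expect_equal(bead_model_gamma0(5, 5, 0.113), 0.0638, tolerance = 1e-3)
})

test_that("consistency chain: plateau-predicted cD equals the quadrature tail amplitude", {
  # noiseless Lorentzian "measured" spectrum: its beta-sweep plateau, fed
  # through the short-range formula, must reproduce the large-t cumulative
  # tail amplitude of the full dispersion integral
  gam_fun <- function(k) 0.08 / (1 + (0.2 * k)^2)
  q <- seq(2 * pi / 4000, 30, by = 2 * pi / 4000)
  sp <- structure(list(q = q, gamma = gam_fun(q),
                       record_length = 4000, dl = 0.1, n_segments = 1L),
                  class = "spectral_density")
  g0 <- plateau(sp)$gamma0
  Dinf <- 1.5
  t_big <- c(2000, 4000)
  tl <- tail_from_spectrum(gam_fun, Dinf, times = t_big)
  amp <- (tl$cumulative$D_um2_per_ms - Dinf) * sqrt(t_big)
  expect_lt(max(abs(amp / predict_cd(g0, Dinf) - 1)), 0.01)
})
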