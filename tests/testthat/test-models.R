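# Analytic model components: Lorentzian, Voigt convolution, EISF, jump
# widths, monodisperse-average and bidisperse spectral models.

test_that("Lorentzian closed forms: peak, HWHM, unit area", {
  omega <- seq(-2000, 2000, length.out = 400001)
  for (g in c(0.05, 1, 12)) {
    L <- lorentzian(omega, g)
    expect_equal(lorentzian(0, g), 1 / (pi * g), tolerance = 1e-12)
    expect_equal(lorentzian(g, g), 0.5 / (pi * g), tolerance = 1e-12)
    # trapezoid area over a wide grid, plus the analytic tail correction
    area <- sum(L) * diff(omega[1:2]) + 2 * (0.5 - atan(2000 / g) / pi)
    expect_equal(area, 1, tolerance = 1e-6)
  }
  expect_error(lorentzian(omega, 0), "gamma > 0")
})

test_that("Voigt profile matches the numerical-convolution oracle", {
  set.seed(4)
  for (k in 1:12) {
    sigma <- runif(1, 0.2, 2)
    gamma <- runif(1, 0.02, 15)
    x <- c(0, sigma / 2, sigma + gamma, 3 * (sigma + gamma))
    v <- voigt_profile(x, sigma, gamma)
    o <- conv_oracle(x, sigma, gamma)
    expect_lt(max(abs(v - o) / o), 1e-7)
  }
})

test_that("Voigt degenerate limits recover Gaussian and Lorentzian", {
  x <- seq(-8, 8, length.out = 201)
  expect_equal(voigt_profile(x, 0.7, 0), dnorm(x, sd = 0.7))
  expect_equal(voigt_profile(x, 0, 1.3), lorentzian(x, 1.3))
  # continuity into the limits
  expect_equal(voigt_profile(x, 0.7, 1e-8), dnorm(x, sd = 0.7),
               tolerance = 1e-6)
  expect_equal(voigt_profile(x, 1e-8, 1.3), lorentzian(x, 1.3),
               tolerance = 1e-6)
})

test_that("resolution convolution: delta terms and area conservation", {
  q <- c(0.5, 1.0)
  res <- resolution_model(q, amp1 = 0.8, sigma1 = 0.4, amp2 = 0.2,
                          sigma2 = 1.2)
  omega <- seq(-4000, 4000, length.out = 400001)
  dw <- diff(omega[1:2])
  # elastic term reproduces the two-Gaussian shape itself
  el <- convolve_with_resolution(list(list(type = "elastic", weight = 2)),
                                 res, 0.5, omega)
  expect_equal(el, 2 * (0.8 * dnorm(omega, sd = 0.4) +
                        0.2 * dnorm(omega, sd = 1.2)))
  # areas of convolved Lorentzians equal their weights
  terms <- list(list(type = "lorentzian", weight = 0.7, gamma = 2),
                list(type = "lorentzian", weight = 0.3, gamma = 9))
  sp <- convolve_with_resolution(terms, res, 1.0, omega)
  expect_true(all(sp >= 0))
  expect_equal(sum(sp) * dw, 1, tolerance = 2e-3)  # fat Lorentzian tails
  expect_error(convolve_with_resolution(terms, res, 0.77, omega),
               "not present")
})

test_that("EISF model: normalization, immobile limit, large-q asymptote", {
  q <- seq(0, 5, by = 0.05)
  expect_equal(eisf_model(0, p = 0.3, phi_mobile = 0.4, R = 10), 1)
  expect_equal(eisf_model(q, p = 1, phi_mobile = 0.5, R = 10),
               rep(1, length(q)))
  # q -> infinity with large R: methyl term -> 1/3, sphere term -> 0
  p <- 0.25; phim <- 0.6
  a_large_q <- eisf_model(60, p, phim, R = 500)
  expect_equal(a_large_q, p + (1 - p) * phim / 3, tolerance = 0.02)
  # monotone decreasing over the instrument range for default parameters
  a <- eisf_model(seq(0.2, 1.9, 0.1), 0.4, 0.3, 10)
  expect_true(all(diff(a) < 0))
  expect_error(eisf_model(q, p = 1.2, phi_mobile = 0.3, R = 10), "\\[0, 1\\]")
})

test_that("jump-diffusion width: Fickian limit, plateau, reference value", {
  D <- 100; tau <- 0.1
  q <- 1e-4
  expect_equal(jump_width(q, D, tau), hbar_ueV_ns * D * q^2,
               tolerance = 1e-6)
  expect_equal(jump_width(1e4, D, tau), hbar_ueV_ns / tau, tolerance = 1e-6)
  # q = 1: hbar * 100 / 11 = 5.98374506 micro-eV
  expect_equal(jump_width(1, D, tau), 5.98374506273, tolerance = 1e-9)
  expect_error(jump_width(1, -5, tau), "> 0")
})

test_that("mono model: A0 = 1 collapses to a single line, beta = 0 to solvent", {
  q <- 1.0
  res <- resolution_model(q, 0.8, 0.4, 0.2, 1.2)
  solv <- solvent_model(q, amplitude = 50, gamma = 80)
  omega <- seq(-30, 30, length.out = 301)
  m1 <- mono_model(beta = 10, gamma_glob = 2, gamma_int = 8, A0 = 1,
                   solv, res, q, omega)
  single <- convolve_with_resolution(
    list(list(type = "lorentzian", weight = 10, gamma = 2)), res, q, omega) +
    convolve_with_resolution(
      list(list(type = "lorentzian", weight = 50, gamma = 80)), res, q, omega)
  expect_equal(m1, single, tolerance = 1e-12)
  m0 <- mono_model(beta = 0, gamma_glob = 2, gamma_int = 8, A0 = 0.5,
                   solv, res, q, omega)
  expect_equal(m0, convolve_with_resolution(
    list(list(type = "lorentzian", weight = 50, gamma = 80)), res, q, omega))
  expect_error(mono_model(1, 2, 8, A0 = 1.4, solv, res, q, omega), "A0")
})

test_that("bidisperse model: degenerate weights/coalescence reduce to mono", {
  q <- 1.0
  res <- resolution_model(q, 0.8, 0.4, 0.2, 1.2)
  solv <- solvent_model(q, amplitude = 50, gamma = 80)
  omega <- seq(-30, 30, length.out = 301)
  gB <- hbar_ueV_ns * 4.5 * q^2
  # s_Ig = 0
  b <- bidisperse_model(4.5, 1.5, s_BSA = 1, s_Ig = 0, beta = 10, A0 = 0.8,
                        gamma_int = 6, solv, res, q, omega)
  m <- mono_model(beta = 10, gamma_glob = gB, gamma_int = 6, A0 = 0.8,
                  solv, res, q, omega)
  expect_equal(b, m, tolerance = 1e-12)
  # D_BSA = D_Ig
  b2 <- bidisperse_model(3, 3, 0.6, 0.4, beta = 10, A0 = 0.8,
                         gamma_int = 6, solv, res, q, omega)
  m2 <- mono_model(beta = 10, gamma_glob = hbar_ueV_ns * 3, gamma_int = 6,
                   A0 = 0.8, solv, res, q, omega)
  expect_equal(b2, m2, tolerance = 1e-12)
})

test_that("bidisperse model equals the hand-built sum of Voigt terms", {
  q <- 1.0
  res <- resolution_model(q, 0.7, 0.35, 0.3, 1.0)
  solv <- solvent_model(q, amplitude = 40, gamma = 100)
  omega <- seq(-30, 30, length.out = 257)
  beta <- 12; A0 <- 0.75; gi <- 5
  gB <- hbar_ueV_ns * 4.5; gI <- hbar_ueV_ns * 1.5
  hand <- 0
  for (comp in list(c(0.7, 0.35), c(0.3, 1.0))) {
    a <- comp[1]; s <- comp[2]
    hand <- hand + a * (
      beta * A0 * (0.6 * voigt_profile(omega, s, gB) +
                   0.4 * voigt_profile(omega, s, gI)) +
      beta * (1 - A0) * voigt_profile(omega, s, gB + gi) +
      40 * voigt_profile(omega, s, 100))
  }
  got <- bidisperse_model(4.5, 1.5, 0.6, 0.4, beta, A0, gi, solv, res, q,
                          omega)
  expect_equal(got, hand, tolerance = 1e-12)
})

test_that("bidisperse model is symmetric under species relabelling", {
  q <- 1.3
  res <- resolution_model(q, 0.8, 0.4, 0.2, 1.2)
  solv <- solvent_model(q, amplitude = 20, gamma = 90)
  omega <- seq(-30, 30, length.out = 201)
  a <- bidisperse_model(4.5, 1.5, 0.6, 0.4, 10, 0.8, 6, solv, res, q, omega)
  b <- bidisperse_model(1.5, 4.5, 0.4, 0.6, 10, 0.8, 6, solv, res, q, omega)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("standalone internal-width mode enforces the broader-line rule", {
  q <- 1
  res <- resolution_model(q, 0.8, 0.4, 0.2, 1.2)
  solv <- solvent_model(q, 10, 80)
  omega <- seq(-30, 30, length.out = 101)
  expect_error(
    bidisperse_model(4.5, 1.5, 0.6, 0.4, 10, 0.8, gamma_int = 1, solv, res,
                     q, omega, internal_width_mode = "standalone"),
    "exceed")
  expect_silent(
    bidisperse_model(4.5, 1.5, 0.6, 0.4, 10, 0.8, gamma_int = 20, solv, res,
                     q, omega, internal_width_mode = "standalone"))
})
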