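# Spectral fitting: q-wise fits, the Fickian check, the global fits and
# their diagnostics, and the internal-dynamics fits.

test_that("q-wise fits on monodisperse data recover hbar*D*q^2 widths", {
  cal <- calib_fixture(nq = 6, nch = 192L)
  comp <- sample_composition(200, 0)   # pure BSA
  truth <- ground_truth(D_BSA = 4.0, D_Ig = 1.0)  # D_Ig unused (s_Ig = 0)
  vf <- volume_fractions(comp)
  sv <- true_solvent(cal, vf[["phi"]])
  sim <- make_mixture_spectra(cal$inst, comp, truth, cal$van$resolution,
                              sv, seed = 51)
  qw <- fit_qwise_average(sim$spectra, cal$res_fit,
                          solvent_fixture(cal, vf[["phi"]]),
                          start = list(D = 3, gamma_int = 5))
  tab <- qw$table
  model <- hbar_ueV_ns * 4.0 * tab$q^2
  expect_true(all(abs(tab$gamma_glob - model) <
                    3 * pmax(tab$gamma_glob_err, 0.02)))
  expect_true(all(tab$converged))
  # Fickian fit on those widths recovers D
  fick <- fit_fickian(tab$gamma_glob, tab$gamma_glob_err, tab$q)
  expect_lt(abs(fick$D_av / 4.0 - 1), 0.05)
  expect_gt(fick$r_squared, 0.99)
  .fixture_cache$qwise_mono <- list(qw = qw, cal = cal, sim = sim, vf = vf)
})

test_that("q-wise fits on bidisperse data give widths between the components", {
  cal <- calib_fixture(nq = 6, nch = 192L)
  comp <- sample_composition(200, 100)
  truth <- ground_truth(4.5, 1.5)
  vf <- volume_fractions(comp)
  sim <- make_mixture_spectra(cal$inst, comp, truth, cal$van$resolution,
                              true_solvent(cal, vf[["phi"]]), seed = 52)
  qw <- fit_qwise_average(sim$spectra, cal$res_fit,
                          solvent_fixture(cal, vf[["phi"]]))
  tab <- qw$table
  lo <- hbar_ueV_ns * 1.5 * tab$q^2
  hi <- hbar_ueV_ns * 4.5 * tab$q^2
  tol <- 3 * pmax(tab$gamma_glob_err, 0.02)
  expect_true(all(tab$gamma_glob > lo - tol & tab$gamma_glob < hi + tol))
})

test_that("zero-protein spectra are flagged degenerate in q-wise fits", {
  cal <- calib_fixture(nq = 6, nch = 192L)
  inst <- cal$inst
  null <- make_mixture_spectra(inst, sample_composition(200, 100),
                               ground_truth(beta_q = 0),
                               cal$van$resolution, true_solvent(cal, 0.2),
                               seed = 53)
  qw <- fit_qwise_average(null$spectra, cal$res_fit,
                          solvent_fixture(cal, 0.2))
  expect_true(all(qw$table$degenerate))
})

test_that("Fickian fit: exact input, heteroscedastic simulation, guards", {
  q <- seq(0.2, 1.9, length.out = 12)
  g <- hbar_ueV_ns * 3.7 * q^2
  f <- fit_fickian(g, rep(0.01, 12), q)
  expect_equal(f$D_av, 3.7, tolerance = 1e-12)
  # heteroscedastic noise: slope within 3 sigma over 100 seeds
  pulls <- vapply(1:100, function(s) {
    err <- 0.02 * (1 + 3 * q)
    gn <- with_seed(1000 + s, g + rnorm(12, sd = err))
    fn <- fit_fickian(gn, err, q)
    (fn$D_av - 3.7) / fn$D_av_err
  }, numeric(1))
  expect_lt(mean(abs(pulls) > 3), 0.05)
  expect_lt(abs(mean(pulls)), 0.5)
  expect_error(fit_fickian(g[1:2], rep(0.01, 2), q[1:2]), "fewer than 3")
})

test_that("global bidisperse fit recovers the generating pair", {
  cal <- calib_fixture(nq = 10, nch = 256L)
  r <- sim_and_fit(cal, sample_composition(200, 100),
                   ground_truth(4.5, 1.5), seed = 54)
  expect_lt(abs(r$fit$D[["D_BSA"]] / 4.5 - 1), 0.10)
  expect_lt(abs(r$fit$D[["D_Ig"]] / 1.5 - 1), 0.10)
  expect_true(r$fit$D[["D_Ig"]] < r$fit$D[["D_BSA"]])
  expect_false(r$fit$degenerate)
  # EISF profile is monotone non-increasing by construction
  expect_true(all(diff(r$fit$A0) <= 1e-9))
  # objective improved on the starting value and parameter bookkeeping
  expect_lt(r$fit$deviance, r$fit$trace[1])
  expect_equal(r$fit$n_par, 4L + 2L * 10L)
  .fixture_cache$bi_fit_example <- r
})

test_that("fit on monodisperse data flags coalescence of the D pair", {
  cal <- calib_fixture(nq = 10, nch = 256L)
  # truly monodisperse signal fitted with the bidisperse model
  comp <- sample_composition(200, 100)
  truth <- ground_truth(D_BSA = 3.000001, D_Ig = 3.0)
  r <- sim_and_fit(cal, comp, truth, seed = 55,
                   start = list(D_BSA = 3.5, D_Ig = 2.5, D_int = 100,
                                tau = 0.1))
  expect_true(r$fit$degenerate)
  expect_lt(abs(r$fit$D[["D_BSA"]] - r$fit$D[["D_Ig"]]),
            3 * sqrt(sum(r$fit$se^2)) + 0.3)
})

test_that("robustness scan: minimum at the optimum, convex, interval-consistent", {
  r <- .fixture_cache$bi_fit_example
  cal <- calib_fixture(nq = 10, nch = 256L)
  solv <- solvent_fixture(cal, r$vf[["phi"]])
  fit <- r$fit
  DI <- fit$D[["D_Ig"]]; se <- fit$se[["D_Ig"]]
  grid <- DI + se * seq(-3, 3, length.out = 7)
  prof <- robustness_scan(fit, r$sim$spectra, cal$res_fit, solv,
                          "D_Ig", grid)
  # minimum of the profile sits at the fitted value
  expect_equal(grid[which.min(prof$deviance)], grid[4])
  # convex around the optimum
  d2 <- diff(diff(prof$deviance))
  expect_true(all(d2 > 0))
  # profile-based 1-sigma (deviance + 1) consistent with the reported se
  half <- prof$deviance - min(prof$deviance)
  right <- approx(half[4:7], grid[4:7], xout = 1)$y
  expect_lt(abs((right - DI) / se - 1), 0.3)
  # out-of-bounds grid values are clipped with a warning
  expect_warning(robustness_scan(fit, r$sim$spectra, cal$res_fit, solv,
                                 "D_Ig", c(-1, DI)), "clipped")
})

test_that("internal-dynamics fits recover EISF and jump parameters", {
  q <- seq(0.2, 1.9, length.out = 16)
  truth <- list(p = 0.4, phi_mobile = 0.3, R = 10, D_int = 100, tau = 0.1)
  A0 <- eisf_model(q, truth$p, truth$phi_mobile, truth$R)
  gi <- jump_width(q, truth$D_int, truth$tau)
  A0_err <- rep(0.01, 16); gi_err <- 0.04 * gi
  res <- with_seed(61, fit_internal_dynamics(
    q, A0 + rnorm(16, sd = A0_err), A0_err,
    gi + rnorm(16, sd = gi_err), gi_err))
  for (k in 1:3) {
    tr <- unlist(truth[c("p", "phi_mobile", "R")])[k]
    expect_lt(abs(res$eisf$estimate[k] - tr), 3 * res$eisf$se[k] + 1e-6)
  }
  expect_lt(abs(res$jump$estimate[1] - 100), 3 * res$jump$se[1])
  expect_lt(abs(res$jump$estimate[2] - 0.1), 3 * res$jump$se[2])
})

test_that("constant internal dynamics show no trend against mixing ratio", {
  q <- seq(0.2, 1.9, length.out = 16)
  ys <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  ests <- t(vapply(seq_along(ys), function(i) {
    A0 <- eisf_model(q, 0.4, 0.3, 10)
    gi <- jump_width(q, 100, 0.1)
    r <- with_seed(70 + i, fit_internal_dynamics(
      q, A0 + rnorm(16, sd = 0.01), rep(0.01, 16),
      gi + rnorm(16, sd = 0.04 * gi), 0.04 * gi))
    c(r$eisf$estimate[3], r$jump$estimate)
  }, numeric(3)))
  # weighted slope of each parameter vs y consistent with zero
  for (k in 1:3) {
    sl <- coef(summary(lm(ests[, k] ~ ys)))[2, ]
    expect_lt(abs(sl["Estimate"] / sl["Std. Error"]), 3)
  }
  # R stays near 10 Angstrom
  expect_true(all(abs(ests[, 1] - 10) < 1.5))
})
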