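# Synthetic-data generators: statistical structure, bookkeeping
# invariants, degenerate compositions.

test_that("vanadium generator: identity case and parameter recovery", {
  inst <- instrument_config(q_grid = c(0.5, 1.0), channel_count = 256L)
  # single Gaussian (second amplitude 0): fitted FWHM recovers the truth
  van <- make_resolution(inst, widths = list(amp1 = 1, sigma1 = 0.4,
                                             amp2 = 1e-9, sigma2 = 2),
                         counts_scale = 1e5, seed = 31)
  fit <- fit_resolution(van$spectra)
  rep <- attr(fit, "report")
  fwhm <- 2 * sqrt(2 * log(2)) * rep$sigma1
  expect_equal(fwhm, rep(2 * sqrt(2 * log(2)) * 0.4, 2), tolerance = 0.01)
  # two-component recovery within 3 sigma of the estimated errors
  van2 <- make_resolution(inst, widths = list(amp1 = 0.7, sigma1 = 0.35,
                                              amp2 = 0.3, sigma2 = 1.0),
                          counts_scale = 1e5, seed = 32)
  fit2 <- fit_resolution(van2$spectra)
  rep2 <- attr(fit2, "report")
  expect_true(all(abs(rep2$sigma1 - 0.35) < 3 * rep2$sigma1_err))
  expect_true(all(abs(rep2$sigma2 - 1.00) < 3 * rep2$sigma2_err))
  expect_true(all(abs(rep2$amp1 / (rep2$amp1 + rep2$amp2) - 0.7) < 0.01))
  # invalid widths name the q index
  expect_error(make_resolution(inst, widths = list(amp1 = 1, sigma1 = -1,
                                                   amp2 = 0, sigma2 = 1)),
               "q index 1, 2")
})

test_that("law of large numbers: sampled counts converge on the model", {
  inst <- instrument_config(q_grid = 1.0, channel_count = 128L)
  van <- make_resolution(inst, counts_scale = 1e7, seed = 33)
  big <- van$expected >= 1e5
  expect_lt(max(abs(van$spectra$counts[big] - van$expected[big]) /
                van$expected[big]), 0.01)
})

test_that("expected counts equal the analytic model area over the window", {
  inst <- instrument_config(q_grid = c(0.6, 1.4), channel_count = 200L)
  cal <- list(res = resolution_model(inst$q_grid, 0.8, 0.4, 0.2, 1.2))
  solv <- solvent_model(inst$q_grid, 5000, d2o_width(inst$q_grid))
  truth <- ground_truth()
  comp <- sample_composition(200, 100)
  sim <- make_mixture_spectra(inst, comp, truth, cal$res, solv, seed = 34)
  A0 <- sim$A0; gi <- sim$gamma_int
  for (i in seq_along(inst$q_grid)) {
    qi <- inst$q_grid[i]
    dens <- function(w)
      bidisperse_model(truth$D_BSA, truth$D_Ig, sim$weights[["s_BSA"]],
                       sim$weights[["s_Ig"]], beta = sim$beta_q[i],
                       A0 = A0[i], gamma_int = gi[i], solvent = solv,
                       resolution = cal$res, q = qi, omega_grid = w)
    area <- integrate(dens, -30, 0, rel.tol = 1e-10)$value +
            integrate(dens, 0, 30, rel.tol = 1e-10)$value
    expect_equal(sum(sim$expected[i, ]), area, tolerance = 1e-6)
  }
})

test_that("generated spectra are invariant under species relabelling", {
  inst <- instrument_config(q_grid = c(0.5, 1.0, 1.5), channel_count = 128L)
  res <- resolution_model(inst$q_grid, 0.8, 0.4, 0.2, 1.2)
  solv <- solvent_model(inst$q_grid, 5000, d2o_width(inst$q_grid))
  orig <- make_mixture_spectra(inst, sample_composition(200, 100),
                               ground_truth(4.5, 1.5), res, solv, seed = 35)
  w <- orig$weights
  # rebuild the noise-free model with the (weight, D) pairs relabelled:
  # the generator's spectra must be unchanged
  for (i in seq_along(inst$q_grid)) {
    qi <- inst$q_grid[i]
    relab <- biqens:::bin_integrate(function(om)
      bidisperse_model(D_BSA = 1.5, D_Ig = 4.5,
                       s_BSA = w[["s_Ig"]], s_Ig = w[["s_BSA"]],
                       beta = orig$beta_q[i], A0 = orig$A0[i],
                       gamma_int = orig$gamma_int[i], solvent = solv,
                       resolution = res, q = qi, omega_grid = om),
      inst$omega_edges)
    expect_equal(orig$expected[i, ], relab, tolerance = 1e-12)
  }
})

test_that("degenerate compositions: c_Ig = 0 is monodisperse, beta = 0 is solvent-only", {
  inst <- instrument_config(q_grid = c(0.7, 1.2), channel_count = 128L)
  res <- resolution_model(inst$q_grid, 0.8, 0.4, 0.2, 1.2)
  solv <- solvent_model(inst$q_grid, 5000, d2o_width(inst$q_grid))
  truth <- ground_truth(D_BSA = 4.0, D_Ig = 1.0)
  mono <- make_mixture_spectra(inst, sample_composition(200, 0), truth,
                               res, solv, seed = 36)
  edges <- inst$omega_edges
  for (i in 1:2) {
    qi <- inst$q_grid[i]
    expect_mono <- biqens:::bin_integrate(function(w)
      mono_model(beta = mono$beta_q[i],
                 gamma_glob = hbar_ueV_ns * 4.0 * qi^2,
                 gamma_int = mono$gamma_int[i], A0 = mono$A0[i],
                 solvent = solv, resolution = res, q = qi, omega_grid = w),
      edges)
    expect_equal(mono$expected[i, ], expect_mono, tolerance = 1e-10)
  }
  # zero protein amplitude: solvent-shaped spectra only
  null <- make_mixture_spectra(inst, sample_composition(200, 100),
                               ground_truth(beta_q = 0), res, solv,
                               seed = 37)
  solv_only <- t(vapply(1:2, function(i) biqens:::bin_integrate(function(w)
    biqens:::solvent_term(solv, res, inst$q_grid[i], w), edges),
    numeric(inst$channel_count)))
  expect_equal(null$expected, solv_only, tolerance = 1e-12)
})

test_that("missing solvent q values are reported", {
  inst <- instrument_config(q_grid = c(0.5, 1.0), channel_count = 64L)
  res <- resolution_model(inst$q_grid, 0.8, 0.4, 0.2, 1.2)
  solv <- solvent_model(0.5, 5000, 40)
  expect_error(make_mixture_spectra(inst, sample_composition(200, 100),
                                    ground_truth(), res, solv, seed = 1),
               "missing q values: 1")
})

test_that("mean of many Poisson realizations matches the model (chi2/dof near 1)", {
  inst <- instrument_config(q_grid = 1.0, channel_count = 128L)
  res <- resolution_model(1.0, 0.8, 0.4, 0.2, 1.2)
  solv <- solvent_model(1.0, 5000, d2o_width(1.0))
  truth <- ground_truth(counts_scale = 2000)
  K <- 60
  tot <- 0
  for (s in 1:K) {
    sim <- make_mixture_spectra(inst, sample_composition(200, 100), truth,
                                res, solv, seed = 4000 + s)
    tot <- tot + sim$spectra$counts
  }
  mu <- K * sim$expected
  chi2 <- sum((tot - mu)^2 / mu) / length(mu)
  expect_gt(chi2, 0.8); expect_lt(chi2, 1.2)
})

test_that("ground truth validates its invariants", {
  expect_error(ground_truth(D_BSA = 1, D_Ig = 2), "D_Ig < D_BSA")
  expect_error(ground_truth(D_int = -1), "> 0")
  expect_error(ground_truth(eisf = list(p = 1.5, phi_mobile = 0.2, R = 10,
                                        a = 1.715)), "\\[0, 1\\]")
})
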