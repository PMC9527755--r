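# Shared synthetic fixtures.  Calibration measurements (vanadium, D2O)
# are expensive to fit, and in a real campaign they are measured once and
# reused for every sample; the cache mirrors that.

.fixture_cache <- new.env(parent = emptyenv())

with_seed <- biqens:::with_seed

# instrument + generated calibrations + fitted resolution, memoized
calib_fixture <- function(nq = 10, nch = 256L, seed = 99L) {
  key <- paste(nq, nch, seed, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  inst <- instrument_config(q_grid = seq(0.2, 1.9, length.out = nq),
                            channel_count = nch)
  van <- make_resolution(inst, counts_scale = 1e5, background = 2,
                         seed = seed)
  d2o <- make_d2o(inst, van$resolution, amplitude = 2e5, seed = seed + 1L)
  res_fit <- fit_resolution(van$spectra)
  out <- list(inst = inst, van = van, d2o = d2o, res_fit = res_fit)
  .fixture_cache[[key]] <- out
  out
}

# frozen solvent for a given total volume fraction, memoized per calib
solvent_fixture <- function(cal, phi) {
  key <- paste("solv", length(cal$inst$q_grid), cal$inst$channel_count,
               round(phi, 6), sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  out <- fix_solvent(cal$d2o$spectra, cal$res_fit, phi_total = phi)
  .fixture_cache[[key]] <- out
  out
}

# exact (generator-side) solvent model scaled to a sample's phi
true_solvent <- function(cal, phi) {
  solvent_model(cal$d2o$solvent$q,
                cal$d2o$solvent$amplitude * (1 - phi),
                cal$d2o$solvent$gamma)
}

# simulate one mixture and run the global bidisperse fit
sim_and_fit <- function(cal, comp, truth, seed, mode = "bidisperse",
                        exact_calibration = FALSE, n_starts = 1L,
                        start = NULL) {
  vf <- volume_fractions(comp)
  sv <- true_solvent(cal, vf[["phi"]])
  sim <- make_mixture_spectra(cal$inst, comp, truth, cal$van$resolution,
                              sv, seed = seed)
  res <- if (exact_calibration) cal$van$resolution else cal$res_fit
  solv <- if (exact_calibration) sv else solvent_fixture(cal, vf[["phi"]])
  if (is.null(start))
    start <- list(D_BSA = 4, D_Ig = 1.8, D_av = 2.5,
                  D_int = 100, tau = 0.1)
  fit <- fit_global(sim$spectra, res, solv, sim$weights, mode = mode,
                    start = start, n_starts = n_starts, seed = seed)
  list(sim = sim, fit = fit, vf = vf)
}

# brute-force numerical Gaussian (x) Lorentzian convolution at one point,
# via adaptive quadrature: the independent Voigt oracle
conv_oracle <- function(x, sigma, gamma) {
  vapply(x, function(xi)
    stats::integrate(function(u)
      stats::dnorm(u, sd = sigma) * (gamma / pi) / (gamma^2 + (xi - u)^2),
      -Inf, Inf, rel.tol = 1e-11, abs.tol = 0)$value,
    numeric(1))
}

# composition with a given total phi (dry scale) and mixing ratio y
composition_for <- function(phi, y, T = 295, bsa = bsa_species(),
                            ig = ig_species()) {
  sample_composition(c_BSA = 1000 * phi * y / bsa$nu,
                     c_Ig = 1000 * phi * (1 - y) / ig$nu, T = T)
}
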