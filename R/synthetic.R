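## Synthetic-data generators: vanadium (resolution), empty can, pure D2O,
## and protein-mixture spectra with the exact statistical structure the
## fitting stages assume (Poisson counts on an energy-channel grid).
## Expected counts per channel are exact bin integrals of the continuous
## model (3-point Gauss-Legendre per channel, composite error ~1e-10), so
## total expected counts match the analytic model area to high precision.

## internal: integrate a density over every channel, 3-pt Gauss-Legendre
bin_integrate <- function(density_fun, edges) {
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  mid <- (lo + hi) / 2
  half <- (hi - lo) / 2
  nodes <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  wts <- c(5, 8, 5) / 9
  x <- c(mid + half * nodes[1], mid + half * nodes[2], mid + half * nodes[3])
  f <- density_fun(x)
  n <- length(mid)
  half * (wts[1] * f[1:n] + wts[2] * f[(n + 1):(2 * n)] +
          wts[3] * f[(2 * n + 1):(3 * n)])
}

#' Ground truth for synthetic mixture spectra
#'
#' The stated world of the generator: apparent diffusion coefficients of
#' the two proteins, internal jump-diffusion parameters, EISF parameters,
#' and counting-scale settings.  Defaults are the scales reported for
#' concentrated BSA/Ig solutions: D_BSA = 4.5, D_Ig = 1.5 Angstrom^2/ns,
#' D_int = 100 Angstrom^2/ns, tau = 0.1 ns, EISF (p, phi_mobile, R) =
#' (0.4, 0.3, 10 Angstrom), peak ~1e4 counts.
#'
#' @param D_BSA,D_Ig apparent diffusion coefficients (Angstrom^2/ns),
#'   \code{D_Ig < D_BSA}.
#' @param D_int,tau internal jump-diffusion coefficient (Angstrom^2/ns)
#'   and residence time (ns).
#' @param eisf list with \code{p}, \code{phi_mobile}, \code{R}, \code{a}.
#' @param beta_q optional per-q protein amplitudes (area counts); when
#'   \code{NULL} they are set so the protein peak channel has
#'   \code{counts_scale} expected counts.
#' @param counts_scale expected peak counts (sets beta_q when unset).
#' @return object of class \code{"ground_truth"}.
#' @export
ground_truth <- function(D_BSA = 4.5, D_Ig = 1.5, D_int = 100, tau = 0.1,
                         eisf = list(p = 0.4, phi_mobile = 0.3, R = 10,
                                     a = 1.715),
                         beta_q = NULL, counts_scale = 1e4) {
  if (!(D_Ig < D_BSA)) stop("ground truth requires D_Ig < D_BSA")
  if (any(c(D_BSA, D_Ig, D_int, tau) <= 0))
    stop("all diffusion parameters must be > 0")
  if (eisf$p < 0 || eisf$p > 1 || eisf$phi_mobile < 0 || eisf$phi_mobile > 1)
    stop("EISF fractions must lie in [0, 1]")
  structure(list(D_BSA = D_BSA, D_Ig = D_Ig, D_int = D_int, tau = tau,
                 eisf = eisf, beta_q = beta_q, counts_scale = counts_scale),
            class = "ground_truth")
}

#' Generate a vanadium-like resolution measurement
#'
#' The noise-free intensity at each q is a two-Gaussian mixture (sharp
#' core plus broad pedestal); counts are Poisson samples of its channel
#' integrals scaled so the peak channel has \code{counts_scale} expected
#' counts.
#'
#' @param config an \code{\link{instrument_config}}.
#' @param widths data.frame (or list) with per-q columns \code{amp1},
#'   \code{sigma1}, \code{amp2}, \code{sigma2} (recycled across q).
#' @param counts_scale expected counts in the peak channel.
#' @param background flat background expected counts per channel (e.g.
#'   the sample can, not yet subtracted).
#' @param seed integer RNG seed for the Poisson sampling.
#' @return list with \code{spectra} (a \code{spectrum_set}),
#'   \code{resolution} (the exact \code{\link{resolution_model}} used) and
#'   \code{expected} (noise-free counts matrix).
#' @export
make_resolution <- function(config, widths = list(amp1 = 0.8, sigma1 = 0.4,
                                                  amp2 = 0.2, sigma2 = 1.2),
                            counts_scale = 1e4, background = 0, seed = 1L) {
  res <- resolution_model(config$q_grid, widths$amp1, widths$sigma1,
                          widths$amp2, widths$sigma2)
  expected <- matrix(0, length(config$q_grid), config$channel_count)
  for (i in seq_along(config$q_grid)) {
    p <- res$pars[i, ]
    u <- bin_integrate(function(w)
      p["amp1"] * dnorm(w, sd = p["sigma1"]) +
      p["amp2"] * dnorm(w, sd = p["sigma2"]), config$omega_edges)
    expected[i, ] <- counts_scale * u / max(u) + background
  }
  counts <- with_seed(seed, matrix(rpois(length(expected), expected),
                                   nrow = nrow(expected)))
  sp <- spectrum_set(config$q_grid, config$omega_grid, counts,
                     meta = list(kind = "vanadium", seed = seed,
                                 counts_scale = counts_scale))
  list(spectra = sp, resolution = res, expected = expected)
}

#' Generate a pure-D2O (solvent) measurement
#'
#' One broad Lorentzian per q (width from D2O self-diffusion by default)
#' convolved with the resolution.
#'
#' @inheritParams make_resolution
#' @param resolution a \code{\link{resolution_model}} on the config's q grid.
#' @param amplitude per-q solvent line areas (counts scale).
#' @param gamma per-q Lorentzian HWHM (micro-eV); default
#'   \code{\link{d2o_width}}.
#' @param background flat background expected counts per channel.
#' @return list with \code{spectra}, \code{solvent} (the exact
#'   \code{\link{solvent_model}}), \code{expected}.
#' @export
make_d2o <- function(config, resolution, amplitude = 2e5,
                     gamma = d2o_width(config$q_grid), background = 0,
                     seed = 2L) {
  solv <- solvent_model(config$q_grid, amplitude, gamma)
  expected <- matrix(0, length(config$q_grid), config$channel_count)
  for (i in seq_along(config$q_grid)) {
    qi <- config$q_grid[i]
    expected[i, ] <- bin_integrate(function(w)
      solvent_term(solv, resolution, qi, w), config$omega_edges) + background
  }
  counts <- with_seed(seed, matrix(rpois(length(expected), expected),
                                   nrow = nrow(expected)))
  sp <- spectrum_set(config$q_grid, config$omega_grid, counts,
                     meta = list(kind = "d2o", seed = seed))
  list(spectra = sp, solvent = solv, expected = expected)
}

#' Generate an empty-can measurement
#'
#' Flat expected counts per channel (aluminium scattering is featureless
#' on the micro-eV window).
#'
#' @inheritParams make_resolution
#' @param level expected counts per channel (recycled across q).
#' @return list with \code{spectra} and \code{expected}.
#' @export
make_empty_can <- function(config, level = 2, seed = 3L) {
  expected <- matrix(rep_len(level, length(config$q_grid)),
                     length(config$q_grid), config$channel_count)
  counts <- with_seed(seed, matrix(rpois(length(expected), expected),
                                   nrow = nrow(expected)))
  sp <- spectrum_set(config$q_grid, config$omega_grid, counts,
                     meta = list(kind = "empty_can", seed = seed))
  list(spectra = sp, expected = expected)
}

#' Generate protein-mixture spectra
#'
#' The noise-free model is the bidisperse spectral model: resolution
#' convolved with the cross-section-weighted sum of the two protein
#' Lorentzians (widths \eqn{\hbar D_i q^2}), a shared internal line with
#' jump-diffusion widths and EISF weighting, plus the solvent line;
#' counts are Poisson-sampled channel integrals.  The generating
#' \code{\link{ground_truth}} is stored in the metadata for recovery
#' tests.
#'
#' @inheritParams make_d2o
#' @param composition a \code{\link{sample_composition}}.
#' @param truth a \code{\link{ground_truth}}.
#' @param solvent a \code{\link{solvent_model}} covering every q of
#'   \code{config} (already scaled to the sample's volume fraction).
#' @param bsa,ig \code{\link{protein_species}} defaults.
#' @param background flat background expected counts per channel (e.g. a
#'   not-yet-subtracted empty can); default 0.
#' @param internal_width_mode see \code{\link{bidisperse_model}}.
#' @return list with \code{spectra}, \code{expected}, \code{weights},
#'   \code{beta_q}.
#' @export
make_mixture_spectra <- function(config, composition, truth, resolution,
                                 solvent, seed = 4L,
                                 bsa = bsa_species(), ig = ig_species(),
                                 background = 0,
                                 internal_width_mode = "additive") {
  missing_q <- config$q_grid[!vapply(config$q_grid, function(q)
    any(abs(solvent$q - q) < 1e-9), logical(1))]
  if (length(missing_q))
    stop("solvent model missing q values: ",
         paste(format(missing_q), collapse = ", "))
  w <- incoherent_weights(composition, bsa, ig)
  nq <- length(config$q_grid)
  A0 <- eisf_model(config$q_grid, truth$eisf$p, truth$eisf$phi_mobile,
                   truth$eisf$R, truth$eisf$a)
  g_int <- jump_width(config$q_grid, truth$D_int, truth$tau)
  beta_q <- truth$beta_q
  expected <- matrix(0, nq, config$channel_count)
  betas <- numeric(nq)
  for (i in seq_len(nq)) {
    qi <- config$q_grid[i]
    protein_unit <- bin_integrate(function(wv)
      bidisperse_model(truth$D_BSA, truth$D_Ig, w["s_BSA"], w["s_Ig"],
                       beta = 1, A0 = A0[i], gamma_int = g_int[i],
                       solvent = solvent_model(qi, 0, 1),
                       resolution = resolution, q = qi, omega_grid = wv,
                       internal_width_mode = internal_width_mode),
      config$omega_edges)
    betas[i] <- if (is.null(beta_q)) truth$counts_scale / max(protein_unit)
                else rep_len(beta_q, nq)[i]
    solv_counts <- bin_integrate(function(wv)
      solvent_term(solvent, resolution, qi, wv), config$omega_edges)
    expected[i, ] <- betas[i] * protein_unit + solv_counts +
      rep_len(background, nq)[i]
  }
  counts <- with_seed(seed, matrix(rpois(length(expected), expected),
                                   nrow = nrow(expected)))
  sp <- spectrum_set(config$q_grid, config$omega_grid, counts,
                     meta = list(kind = "mixture", seed = seed,
                                 T = composition$T,
                                 c_BSA = composition$c_BSA,
                                 c_Ig = composition$c_Ig,
                                 D_BSA = truth$D_BSA, D_Ig = truth$D_Ig,
                                 D_int = truth$D_int, tau = truth$tau))
  list(spectra = sp, expected = expected, weights = w, beta_q = betas,
       A0 = A0, gamma_int = g_int)
}
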