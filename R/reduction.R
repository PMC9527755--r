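## Data reduction: empty-can subtraction, per-q two-Gaussian resolution
## fits on vanadium, solvent fixing from pure D2O.  Error model: Poisson
## sigma = sqrt(counts) on raw spectra, quadrature propagation thereafter.

#' Subtract the empty-can contribution
#'
#' \code{counts_out = counts_sample - scale * counts_empty}; uncertainties
#' propagate in quadrature, negative channels are clipped to zero and the
#' number of clipped channels is recorded in the metadata.
#'
#' @param sample,empty \code{\link{spectrum_set}}s on identical grids.
#' @param scale can transmission/self-shielding factor (default 1: the
#'   experiment states none).
#' @return a \code{spectrum_set}; \code{meta$clipped_channels} counts the
#'   channels clipped at zero, \code{meta$can_scale} records the factor.
#' @export
subtract_empty_can <- function(sample, empty, scale = 1) {
  stopifnot(inherits(sample, "spectrum_set"), inherits(empty, "spectrum_set"))
  if (!grids_match(sample, empty))
    stop("sample and empty-can spectra are on different (q, omega) grids")
  counts <- sample$counts - scale * empty$counts
  clipped <- sum(counts < 0)
  counts[counts < 0] <- 0
  errors <- sqrt(sample$errors^2 + scale^2 * empty$errors^2)
  meta <- sample$meta
  meta$clipped_channels <- clipped
  meta$can_scale <- scale
  spectrum_set(sample$q, sample$omega, counts, errors, meta)
}

#' Fit the instrument resolution from a vanadium measurement
#'
#' Per momentum transfer, fits a sum of two zero-centred Gaussians plus a
#' flat background by Poisson maximum likelihood: the two component
#' widths are optimized (Nelder-Mead on log widths) with the nonnegative
#' amplitudes profiled out by IRLS.
#'
#' The reported reduced chi-square is the deviance divided by the number
#' of channels with non-negligible expected counts (mu >= 0.5) minus the
#' parameter count; channels with vanishing expectation contribute
#' essentially zero deviance and would otherwise deflate the statistic.
#'
#' @param vanadium a \code{\link{spectrum_set}} (counts of an elastic
#'   scatterer).
#' @param start optional list with starting \code{sigma1}, \code{sigma2}
#'   (micro-eV).
#' @return a \code{\link{resolution_model}} with attribute
#'   \code{"report"}: a data.frame of per-q parameters, 1-sigma
#'   uncertainties, background level and reduced chi-square.
#' @export
fit_resolution <- function(vanadium, start = list(sigma1 = 0.4, sigma2 = 1.2)) {
  stopifnot(inherits(vanadium, "spectrum_set"))
  omega <- vanadium$omega
  edges <- omega_edges_from_centres(omega)
  nq <- length(vanadium$q)
  pars <- matrix(NA_real_, nq, 4,
                 dimnames = list(NULL, c("amp1", "sigma1", "amp2", "sigma2")))
  rep_rows <- vector("list", nq)
  for (i in seq_len(nq)) {
    y <- vanadium$counts[i, ]
    if (all(y <= 0)) stop("vanadium counts are all zero at q = ", vanadium$q[i])
    basis <- function(s) cbind(
      bin_integrate(function(w) dnorm(w, sd = s[1]), edges),
      bin_integrate(function(w) dnorm(w, sd = s[2]), edges),
      1)                                 # flat background, counts/channel
    obj <- function(th) irls_amplitudes(y, basis(exp(th)))$deviance
    opt <- stats::optim(log(c(start$sigma1, start$sigma2)), obj,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-9, maxit = 1000))
    if (opt$convergence != 0)
      stop("resolution fit did not converge at q = ", vanadium$q[i])
    s <- exp(opt$par)
    # order components: sigma1 = sharp core
    if (s[1] > s[2]) s <- rev(s)
    fit <- irls_amplitudes(y, basis(s))
    a <- fit$a
    dof <- sum(fit$mu >= 0.5) - 5L
    # parameter errors: Gaussian approximation around the optimum
    se_sigma <- sigma_errors_fd(obj, log(s))
    atot <- a[1] + a[2]
    pars[i, ] <- c(a[1] / atot, s[1], a[2] / atot, s[2])
    rep_rows[[i]] <- data.frame(
      q = vanadium$q[i], amp1 = a[1], amp2 = a[2],
      sigma1 = s[1], sigma2 = s[2],
      sigma1_err = se_sigma[1] * s[1], sigma2_err = se_sigma[2] * s[2],
      background = a[3], chi2_nu = fit$deviance / dof)
  }
  res <- resolution_model(vanadium$q, pars[, "amp1"], pars[, "sigma1"],
                          pars[, "amp2"], pars[, "sigma2"])
  attr(res, "report") <- do.call(rbind, rep_rows)
  res
}

## internal: 1-sigma errors of optim parameters from a finite-difference
## Hessian of a deviance-scale objective (cov = 2 H^-1)
sigma_errors_fd <- function(obj, par, h = 1e-3) {
  k <- length(par)
  H <- matrix(0, k, k)
  f0 <- obj(par)
  for (a in seq_len(k)) for (b in seq_len(a)) {
    ea <- eb <- numeric(k); ea[a] <- h; eb[b] <- h
    if (a == b) {
      H[a, a] <- (obj(par + ea) - 2 * f0 + obj(par - ea)) / h^2
    } else {
      H[a, b] <- H[b, a] <-
        (obj(par + ea + eb) - obj(par + ea - eb) -
         obj(par - ea + eb) + obj(par - ea - eb)) / (4 * h^2)
    }
  }
  cov <- tryCatch(2 * solve(H), error = function(e)
    matrix(NA_real_, k, k))
  sqrt(pmax(diag(cov), 0))
}

## internal: reconstruct channel edges from uniform channel centres
omega_edges_from_centres <- function(omega) {
  d <- diff(omega)
  if (max(abs(d - d[1])) > 1e-6 * abs(d[1]))
    stop("non-uniform omega grid")
  c(omega - d[1] / 2, omega[length(omega)] + d[1] / 2)
}

#' Fix the solvent model from a pure D2O measurement
#'
#' Per q, fits one Lorentzian (convolved with the resolution) to the D2O
#' spectrum by Poisson maximum likelihood, then rescales the amplitudes by
#' \code{(1 - phi_total)} (volume displaced by protein).  The returned
#' parameters are frozen for all subsequent sample fits.
#'
#' @param d2o a \code{\link{spectrum_set}} of the pure solvent.
#' @param resolution a \code{\link{resolution_model}} on the same q grid.
#' @param phi_total total protein volume fraction of the sample the model
#'   will be used for, in \[0, 1).
#' @return a \code{\link{solvent_model}} with attribute \code{"report"}
#'   (per-q width, amplitude, uncertainties, reduced chi-square).
#' @export
fix_solvent <- function(d2o, resolution, phi_total = 0) {
  stopifnot(inherits(d2o, "spectrum_set"))
  if (phi_total < 0 || phi_total >= 1)
    stop("phi_total must lie in [0, 1)")
  omega <- d2o$omega
  edges <- omega_edges_from_centres(omega)
  nq <- length(d2o$q)
  amp <- gam <- amp_err <- gam_err <- chi2 <- numeric(nq)
  for (i in seq_len(nq)) {
    qi <- d2o$q[i]
    y <- d2o$counts[i, ]
    # no flat-background nuisance here: for gamma much wider than the
    # energy window it would be fully degenerate with the Lorentzian
    basis <- function(g) cbind(bin_integrate(function(w)
      convolve_with_resolution(list(list(type = "lorentzian", weight = 1,
                                         gamma = g)),
                               resolution, qi, w), edges))
    obj <- function(lg) irls_amplitudes(y, basis(exp(lg)))$deviance
    opt <- stats::optimize(obj, interval = log(c(1e-2, 1e4)), tol = 1e-8)
    g <- exp(opt$minimum)
    fit <- irls_amplitudes(y, basis(g))
    se <- sigma_errors_fd(obj, opt$minimum)
    amp[i] <- fit$a[1]
    gam[i] <- g
    gam_err[i] <- se[1] * g
    amp_err[i] <- sqrt(1 / fit$info[1, 1])  # Fisher info of the amplitude
    chi2[i] <- fit$deviance / (sum(fit$mu >= 0.5) - 2L)
  }
  out <- solvent_model(d2o$q, amp * (1 - phi_total), gam)
  attr(out, "report") <- data.frame(
    q = d2o$q, amplitude_pure = amp, amplitude = amp * (1 - phi_total),
    amplitude_err = amp_err * (1 - phi_total),
    gamma = gam, gamma_err = gam_err, chi2_nu = chi2,
    phi_total = phi_total)
  out
}
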