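## Spectral fitting: q-wise average fits, the global average and
## bidisperse fits sharing diffusion coefficients across all q, the
## Fickian check, model comparison, robustness scans and the
## internal-dynamics (EISF + jump diffusion) fits.
##
## Objective everywhere: the Poisson deviance (-2 log L up to a constant),
## reported as chi2_nu = deviance / dof.  Per-q nuisance amplitudes
## (beta, A0) are profiled out by identity-link IRLS inside the objective;
## the shared parameters are optimized by Nelder-Mead on log scales and
## refined by BFGS, with seeded multi-starts.

## internal: expected-count basis for one q (2-point Gauss-Legendre per
## channel: matches the bin-integrated generator to ~3e-4 relative)
## returns columns: f_glob (global line(s), unit area), f_int (internal)
fit_basis <- function(mode, q, omega, dw, resolution, D1, D2, s1, s2,
                      gamma_int, internal_width_mode) {
  i <- q_index(resolution, q, "resolution model")
  p <- resolution$pars[i, ]
  sig <- c(p["sigma1"], p["sigma2"])
  amp <- c(p["amp1"], p["amp2"])
  n <- length(omega)
  d <- dw / (2 * sqrt(3))
  x <- c(omega - d, omega + d)
  bin2 <- function(v) (v[1:n, , drop = FALSE] +
                       v[(n + 1):(2 * n), , drop = FALSE]) / 2
  if (mode == "average") {
    g <- hbar_ueV_ns * D1 * q^2
    base <- g
    g_tot <- if (internal_width_mode == "additive") base + gamma_int
             else gamma_int
    V <- bin2(voigt_multi(x, rep(sig, 2), rep(c(g, g_tot), each = 2)))
    f1 <- V[, 1:2] %*% amp
    f2 <- V[, 3:4] %*% amp
  } else {
    gB <- hbar_ueV_ns * D1 * q^2
    gI <- hbar_ueV_ns * D2 * q^2
    base <- max(gB, gI)
    g_tot <- if (internal_width_mode == "additive") base + gamma_int
             else gamma_int
    V <- bin2(voigt_multi(x, rep(sig, 3), rep(c(gB, gI, g_tot), each = 2)))
    f1 <- s1 * (V[, 1:2] %*% amp) + s2 * (V[, 3:4] %*% amp)
    f2 <- V[, 5:6] %*% amp
  }
  dw * cbind(f1, f2)
}

## internal: profiled deviance over all q for shared parameters.
## Enforces the monotone non-increasing EISF by a weighted
## pool-adjacent-violators projection of the profiled A0(q), followed by
## a single-amplitude refit at the pooled values.
profile_deviance <- function(theta, mode, sample, resolution, solvent,
                             weights, internal_width_mode, detail = FALSE,
                             monotone_A0 = TRUE, offsets = NULL) {
  q <- sample$q
  omega <- sample$omega
  dw <- omega[2] - omega[1]
  if (mode == "average") {
    D1 <- exp(theta[1]); D2 <- NA
    D_int <- exp(theta[2]); tau <- exp(theta[3])
  } else {
    D2 <- exp(theta[1])                 # D_Ig
    D1 <- D2 + exp(theta[2])            # D_BSA = D_Ig + Delta
    D_int <- exp(theta[3]); tau <- exp(theta[4])
  }
  if (!all(is.finite(c(D1, D_int, tau)))) return(Inf)
  nq <- length(q)
  if (is.null(offsets)) offsets <- solvent_offsets(sample, resolution, solvent)
  a1 <- a2 <- A0 <- wA0 <- dev_q <- n_eff <- numeric(nq)
  Fs <- vector("list", nq)
  offs <- vector("list", nq)
  for (i in seq_len(nq)) {
    gi <- jump_width(q[i], D_int, tau)
    F <- fit_basis(mode, q[i], omega, dw, resolution, D1, D2,
                   weights[1], weights[2], gi, internal_width_mode)
    off <- offsets[[i]]
    fit <- irls_amplitudes(sample$counts[i, ], F, off)
    Fs[[i]] <- F; offs[[i]] <- off
    a1[i] <- fit$a[1]; a2[i] <- fit$a[2]
    tot <- a1[i] + a2[i]
    A0[i] <- if (tot > 0) a1[i] / tot else 1
    # delta-method precision of A0 from the amplitude Fisher information
    cov <- tryCatch(solve(fit$info), error = function(e) diag(Inf, 2))
    gr <- c(a2[i], -a1[i]) / max(tot, 1e-12)^2
    vA <- drop(gr %*% cov %*% gr)
    wA0[i] <- if (is.finite(vA) && vA > 0) 1 / vA else 1e-6
    dev_q[i] <- fit$deviance
    n_eff[i] <- sum(fit$mu >= 0.5)
  }
  if (monotone_A0 && is.unsorted(rev(A0 + 1e-12))) {
    A0m <- pmin(pmax(pava_nonincreasing(A0, wA0), 0), 1)
    for (i in seq_len(nq)) {
      f <- Fs[[i]][, 1] * A0m[i] + Fs[[i]][, 2] * (1 - A0m[i])
      fit <- irls_amplitudes(sample$counts[i, ], cbind(f), offs[[i]])
      beta <- fit$a[1]
      a1[i] <- beta * A0m[i]; a2[i] <- beta * (1 - A0m[i])
      dev_q[i] <- fit$deviance
      n_eff[i] <- sum(fit$mu >= 0.5)
    }
    A0 <- A0m
  }
  dev <- sum(dev_q)
  if (!detail) return(dev)
  list(deviance = dev, dev_q = dev_q, n_eff = sum(n_eff),
       beta = a1 + a2, A0 = A0,
       D_BSA = if (mode == "average") D1 else D1,
       D_Ig = if (mode == "average") NA_real_ else D2,
       D_av = if (mode == "average") D1 else NA_real_,
       D_int = D_int, tau = tau,
       gamma_int = jump_width(q, D_int, tau))
}

## internal: theta-independent per-q solvent expected counts
## (bin-integrated, computed once per fit)
solvent_offsets <- function(sample, resolution, solvent) {
  edges <- omega_edges_from_centres(sample$omega)
  lapply(seq_along(sample$q), function(i)
    bin_integrate(function(w)
      solvent_term(solvent, resolution, sample$q[i], w), edges))
}

#' Global spectral fit sharing diffusion coefficients across all q
#'
#' Fits all momentum transfers simultaneously by Poisson maximum
#' likelihood.  In \code{mode = "average"} one apparent diffusion
#' coefficient D_av is shared across q (the monodisperse-average model);
#' in \code{mode = "bidisperse"} a single pair (D_BSA, D_Ig) is shared,
#' entering as per-q Lorentzian widths \eqn{\hbar D q^2} weighted by the
#' incoherent cross-section weights.  Per-q protein amplitudes beta(q)
#' and the averaged EISF A0(q) (constrained monotonically non-increasing
#' in q) are profiled out; the shared internal line has jump-diffusion
#' widths (D_int, tau).  The bidisperse model therefore has exactly one
#' more free parameter than the average model.  The ordering
#' \code{D_Ig < D_BSA} is enforced by fitting (D_Ig, Delta > 0) with
#' D_BSA = D_Ig + Delta.
#'
#' @param sample reduced \code{\link{spectrum_set}} of the mixture.
#' @param resolution a \code{\link{resolution_model}} (from vanadium).
#' @param solvent a frozen \code{\link{solvent_model}} (from D2O).
#' @param weights incoherent weights \code{c(s_BSA, s_Ig)} from
#'   \code{\link{incoherent_weights}} (bidisperse mode).
#' @param mode \code{"bidisperse"} or \code{"average"}.
#' @param start optional named list of starting values (\code{D_BSA},
#'   \code{D_Ig} or \code{D_av}, \code{D_int}, \code{tau}).
#' @param n_starts number of seeded multi-starts (jittered initials).
#' @param seed RNG seed for the start jitter.
#' @param internal_width_mode see \code{\link{bidisperse_model}}.
#' @param conf_level confidence level of the reported intervals (default
#'   0.68, one sigma).
#' @return object of class \code{"global_fit"}: fitted coefficients with
#'   standard errors and confidence intervals, per-q \code{beta},
#'   \code{A0} and internal widths, \code{chi2_nu}, \code{deviance},
#'   \code{dof}, parameter count \code{n_par}, the monotone objective
#'   trace, and degeneracy flags.
#' @export
fit_global <- function(sample, resolution, solvent,
                       weights = c(s_BSA = 0.5, s_Ig = 0.5),
                       mode = c("bidisperse", "average"),
                       start = NULL, n_starts = 3L, seed = 1L,
                       internal_width_mode = "additive",
                       conf_level = 0.68) {
  mode <- match.arg(mode)
  stopifnot(inherits(sample, "spectrum_set"))
  if (mode == "bidisperse" && abs(sum(weights) - 1) > 1e-6)
    stop("weights must sum to 1")
  offs <- solvent_offsets(sample, resolution, solvent)
  trace_env <- new.env(); trace_env$vals <- numeric(0)
  obj <- function(theta) {
    d <- profile_deviance(theta, mode, sample, resolution, solvent,
                          weights, internal_width_mode, offsets = offs)
    trace_env$vals <- c(trace_env$vals, d)
    d
  }
  ## heuristic starting point
  if (is.null(start)) start <- list()
  D_int0 <- start$D_int %||% 100
  tau0 <- start$tau %||% 0.1
  if (mode == "average") {
    th0 <- log(c(start$D_av %||% 3, D_int0, tau0))
  } else {
    DI0 <- start$D_Ig %||% 1.8
    DB0 <- start$D_BSA %||% 4.0
    if (DB0 <= DI0) stop("infeasible start: D_BSA must exceed D_Ig")
    th0 <- log(c(DI0, DB0 - DI0, D_int0, tau0))
  }
  starts <- with_seed(seed, {
    jit <- lapply(seq_len(max(n_starts - 1L, 0L)), function(k)
      th0 + stats::rnorm(length(th0), sd = 0.35))
    c(list(th0), jit)
  })
  best <- NULL
  for (s0 in starts) {
    o <- stats::optim(s0, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 600))
    o <- stats::optim(o$par, obj, method = "BFGS",
                      control = list(reltol = 1e-10, maxit = 100))
    if (is.null(best) || o$value < best$value) best <- o
  }
  th <- best$par
  det <- profile_deviance(th, mode, sample, resolution, solvent, weights,
                          internal_width_mode, detail = TRUE, offsets = offs)
  nq <- length(sample$q)
  n_par <- length(th) + 2L * nq
  # effective dof: channels with non-negligible expected counts
  dof <- det$n_eff - n_par
  ## uncertainties: finite-difference Hessian of the profiled deviance in
  ## log space, cov = 2 H^-1, delta method to the D scale
  covl <- fd_cov(function(t)
    profile_deviance(t, mode, sample, resolution, solvent, weights,
                     internal_width_mode, offsets = offs), th, h = 2e-3)
  se_log <- sqrt(pmax(diag(covl), 0))
  zc <- stats::qnorm(0.5 + conf_level / 2)
  if (mode == "average") {
    D <- c(D_av = det$D_av)
    se <- c(D_av = det$D_av * se_log[1])
  } else {
    DI <- exp(th[1]); Dd <- exp(th[2])
    # var(D_BSA) = var(DI) + var(Dd) + 2 cov on the natural scale
    J <- rbind(D_Ig = c(DI, 0), D_BSA = c(DI, Dd))
    covD <- J %*% covl[1:2, 1:2] %*% t(J)
    D <- c(D_BSA = DI + Dd, D_Ig = DI)
    se <- c(D_BSA = sqrt(max(covD[2, 2], 0)),
            D_Ig = sqrt(max(covD[1, 1], 0)))
  }
  ci <- cbind(lower = D - zc * se, upper = D + zc * se)
  degenerate <- if (mode == "bidisperse")
    (D["D_BSA"] - D["D_Ig"]) < zc * sqrt(sum(se^2)) else FALSE
  structure(list(
    mode = mode, D = D, se = se, ci = ci, conf_level = conf_level,
    D_int = det$D_int, tau = det$tau,
    se_log = se_log,
    q = sample$q, beta = det$beta, A0 = det$A0, gamma_int = det$gamma_int,
    weights = weights, deviance = det$deviance, dof = dof,
    chi2_nu = det$deviance / dof, n_par = n_par,
    dev_q = det$dev_q, trace = cummin(trace_env$vals),
    degenerate = unname(degenerate),
    theta = th, internal_width_mode = internal_width_mode,
    convergence = best$convergence), class = "global_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## internal: covariance (2 H^-1) of a deviance objective by central FD
fd_cov <- function(obj, par, h = 1e-3) {
  k <- length(par)
  H <- matrix(0, k, k)
  f0 <- obj(par)
  for (a in seq_len(k)) for (b in seq_len(a)) {
    ea <- eb <- numeric(k); ea[a] <- h; eb[b] <- h
    if (a == b) H[a, a] <- (obj(par + ea) - 2 * f0 + obj(par - ea)) / h^2
    else H[a, b] <- H[b, a] <-
      (obj(par + ea + eb) - obj(par + ea - eb) -
       obj(par - ea + eb) + obj(par - ea - eb)) / (4 * h^2)
  }
  tryCatch(2 * solve(H), error = function(e) matrix(NA_real_, k, k))
}

#' @export
print.global_fit <- function(x, ...) {
  cat("<global_fit mode=", x$mode, ">\n", sep = "")
  for (nm in names(x$D))
    cat(sprintf("  %-6s = %.3f +/- %.3f A^2/ns  [%.3f, %.3f]\n", nm,
                x$D[nm], x$se[nm], x$ci[nm, 1], x$ci[nm, 2]))
  cat(sprintf("  D_int  = %.1f A^2/ns, tau = %.3f ns\n", x$D_int, x$tau))
  cat(sprintf("  chi2_nu = %.4f (%d par, %d dof)%s\n", x$chi2_nu,
              x$n_par, x$dof,
              if (isTRUE(x$degenerate)) "  [degenerate: D pair coalesced]"
              else ""))
  invisible(x)
}

#' Simultaneous bidisperse fit (convenience wrapper)
#'
#' \code{fit_global} in bidisperse mode; restarts automatically from
#' permuted initial values if the first attempt fails to converge.
#'
#' @inheritParams fit_global
#' @return a \code{"global_fit"}.
#' @export
fit_bidisperse_global <- function(sample, resolution, solvent, weights,
                                  ...) {
  fit_global(sample, resolution, solvent, weights, mode = "bidisperse", ...)
}

#' q-wise fits of the monodisperse-average model
#'
#' Independent Poisson maximum-likelihood fits per momentum transfer: one
#' global Lorentzian (width gamma_glob), one internal line (additive
#' width gamma_glob + gamma_int), EISF and amplitude profiled out.
#'
#' @inheritParams fit_global
#' @return object of class \code{"qwise_fit"}: a per-q table with
#'   \code{beta}, \code{A0}, \code{gamma_glob}, \code{gamma_int},
#'   1-sigma errors, \code{chi2_nu} and flags (\code{converged},
#'   \code{degenerate} when beta is consistent with 0).
#' @export
fit_qwise_average <- function(sample, resolution, solvent,
                              start = list(D = 3, gamma_int = 5),
                              internal_width_mode = "additive") {
  stopifnot(inherits(sample, "spectrum_set"))
  omega <- sample$omega
  dw <- omega[2] - omega[1]
  rows <- vector("list", length(sample$q))
  for (i in seq_along(sample$q)) {
    qi <- sample$q[i]
    y <- sample$counts[i, ]
    off <- dw * solvent_term(solvent, resolution, qi, omega)
    obj <- function(th) {
      g <- exp(th[1]); gi <- exp(th[2])
      F <- fit_basis("average", qi, omega, dw, resolution,
                     g / (hbar_ueV_ns * qi^2), NA, 1, 0, gi,
                     internal_width_mode)
      irls_amplitudes(y, F, off)$deviance
    }
    th0 <- log(c(hbar_ueV_ns * start$D * qi^2, start$gamma_int))
    opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-9, maxit = 500))
    conv <- opt$convergence == 0
    g <- exp(opt$par[1]); gi <- exp(opt$par[2])
    F <- fit_basis("average", qi, omega, dw, resolution,
                   g / (hbar_ueV_ns * qi^2), NA, 1, 0, gi,
                   internal_width_mode)
    fit <- irls_amplitudes(y, F, off)
    tot <- sum(fit$a)
    cov <- tryCatch(solve(fit$info), error = function(e) diag(Inf, 2))
    se_log <- sigma_errors_fd(obj, opt$par)
    beta_err <- sqrt(max(cov[1, 1] + cov[2, 2] + 2 * cov[1, 2], 0))
    degen <- tot < 3 * beta_err || !is.finite(beta_err)
    rows[[i]] <- data.frame(
      q = qi, beta = tot, beta_err = beta_err,
      A0 = if (tot > 0) fit$a[1] / tot else NA_real_,
      gamma_glob = g, gamma_glob_err = se_log[1] * g,
      gamma_int = gi, gamma_int_err = se_log[2] * gi,
      chi2_nu = fit$deviance / (sum(fit$mu >= 0.5) - 4L),
      converged = conv, degenerate = degen)
  }
  structure(list(table = do.call(rbind, rows),
                 internal_width_mode = internal_width_mode),
            class = "qwise_fit")
}

#' @export
print.qwise_fit <- function(x, ...) {
  cat("<qwise_fit> ", nrow(x$table), " q points\n", sep = "")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Fickian check: weighted fit of gamma = hbar * D * q^2
#'
#' Weighted least-squares slope of the q-wise global widths against q^2
#' through the origin.  The relationship is not imposed on the q-wise
#' fits; when it arises naturally the per-point residuals are small.  At
#' the highest q the finite energy window biases the fitted width low;
#' the residual table makes that deviation visible.
#'
#' @param gamma per-q global HWHM (micro-eV).
#' @param gamma_err 1-sigma errors of \code{gamma}.
#' @param q momentum transfers (1/Angstrom).
#' @param q_max_cut optional upper q limit for the fit (points above are
#'   excluded from the slope but kept in the residual table).
#' @return list with \code{D_av} (Angstrom^2/ns), \code{D_av_err},
#'   \code{residuals} data.frame (per-q observed, model, residual in
#'   sigma units, used flag), and weighted \code{r_squared}.
#' @export
fit_fickian <- function(gamma, gamma_err, q, q_max_cut = Inf) {
  keep <- is.finite(gamma) & is.finite(gamma_err) & gamma_err > 0
  use <- keep & q <= q_max_cut
  if (sum(use) < 3) stop("fewer than 3 usable q points for the Fickian fit")
  x <- q[use]^2
  w <- 1 / gamma_err[use]^2
  slope <- sum(w * x * gamma[use]) / sum(w * x^2)
  slope_err <- sqrt(1 / sum(w * x^2))
  model <- slope * q^2
  resid_sigma <- (gamma - model) / gamma_err
  ybar <- sum(w * gamma[use]) / sum(w)
  r2 <- 1 - sum(w * (gamma[use] - slope * x)^2) /
    sum(w * (gamma[use] - ybar)^2)
  list(D_av = slope / hbar_ueV_ns,
       D_av_err = slope_err / hbar_ueV_ns,
       residuals = data.frame(q = q, gamma = gamma, gamma_err = gamma_err,
                              model = model, resid_sigma = resid_sigma,
                              used = use),
       r_squared = r2)
}

#' Compare the average and bidisperse global fits
#'
#' Reports the reduced chi-square of both models, their parameter counts
#' (the bidisperse model has exactly one more), and the differences.
#'
#' @param mono a \code{"global_fit"} with \code{mode = "average"}.
#' @param bi a \code{"global_fit"} with \code{mode = "bidisperse"}.
#' @return data.frame with one row per model plus attributes
#'   \code{delta_chi2_nu} and \code{delta_n_par}.
#' @export
compare_models <- function(mono, bi) {
  stopifnot(mono$mode == "average", bi$mode == "bidisperse")
  out <- data.frame(model = c("average", "bidisperse"),
                    chi2_nu = c(mono$chi2_nu, bi$chi2_nu),
                    deviance = c(mono$deviance, bi$deviance),
                    n_par = c(mono$n_par, bi$n_par),
                    dof = c(mono$dof, bi$dof))
  attr(out, "delta_chi2_nu") <- bi$chi2_nu - mono$chi2_nu
  attr(out, "delta_n_par") <- bi$n_par - mono$n_par
  out
}

#' Robustness scan of a global fit
#'
#' Re-minimizes the profiled Poisson deviance over all remaining shared
#' parameters while one named parameter is stepped along a grid; the
#' resulting reduced chi-square profile shows how sharply the data
#' constrain that parameter.
#'
#' @param fit a \code{"global_fit"}.
#' @param sample,resolution,solvent the data the fit was run on.
#' @param parameter one of \code{"D_BSA"}, \code{"D_Ig"} (bidisperse),
#'   \code{"D_av"} (average), \code{"D_int"}, \code{"tau"}.
#' @param grid numeric grid of parameter values; values outside the
#'   feasible region are clipped with a warning.
#' @return data.frame with \code{value}, \code{chi2_nu}, \code{deviance}.
#' @export
robustness_scan <- function(fit, sample, resolution, solvent, parameter,
                            grid) {
  stopifnot(inherits(fit, "global_fit"))
  mode <- fit$mode
  valid <- c("D_int", "tau", if (mode == "average") "D_av"
             else c("D_BSA", "D_Ig"))
  if (!parameter %in% valid)
    stop("parameter must be one of: ", paste(valid, collapse = ", "))
  lo <- 1e-6
  hi <- Inf
  if (mode == "bidisperse") {
    if (parameter == "D_Ig") hi <- unname(fit$D["D_BSA"]) * 0.999
    if (parameter == "D_BSA") lo <- unname(fit$D["D_Ig"]) * 1.001
  }
  clipped <- grid < lo | grid > hi
  if (any(clipped)) {
    warning(sum(clipped), " grid value(s) outside bounds were clipped")
    grid <- pmin(pmax(grid, lo), hi)
  }
  th_hat <- fit$theta
  offs <- solvent_offsets(sample, resolution, solvent)
  rows <- lapply(grid, function(v) {
    if (mode == "average") {
      fixed_idx <- switch(parameter, D_av = 1L, D_int = 2L, tau = 3L)
      make_theta <- function(free) {
        th <- numeric(3)
        th[fixed_idx] <- log(v)
        th[-fixed_idx] <- free
        th
      }
    } else {
      make_theta <- switch(parameter,
        D_Ig = function(free) c(log(v), free[1], free[2], free[3]),
        D_BSA = function(free) {
          DI <- exp(free[1])
          c(free[1], log(max(v - DI, 1e-8)), free[2], free[3])
        },
        D_int = function(free) c(free[1], free[2], log(v), free[3]),
        tau = function(free) c(free[1], free[2], free[3], log(v)))
    }
    free0 <- if (mode == "average") th_hat[-switch(parameter, D_av = 1L,
                                                   D_int = 2L, tau = 3L)]
      else switch(parameter,
                  D_Ig = th_hat[2:4],
                  D_BSA = c(min(th_hat[1], log(v * 0.7)), th_hat[3:4]),
                  D_int = th_hat[c(1, 2, 4)],
                  tau = th_hat[1:3])
    o <- stats::optim(free0, function(free)
      profile_deviance(make_theta(free), mode, sample, resolution, solvent,
                       fit$weights, fit$internal_width_mode, offsets = offs),
      method = "Nelder-Mead", control = list(reltol = 1e-8, maxit = 400))
    data.frame(value = v, deviance = o$value,
               chi2_nu = o$value / fit$dof)
  })
  do.call(rbind, rows)
}

#' Fit the internal dynamics: EISF model and jump-diffusion widths
#'
#' Weighted least squares of the EISF model (immobile fraction p,
#' methyl-like fraction phi, confinement radius R; methyl distance a
#' fixed at 1.715 Angstrom) to A0(q), and of the jump-diffusion law to
#' the internal widths gamma_int(q).
#'
#' @param q momentum transfers (1/Angstrom).
#' @param A0,A0_err averaged EISF values and 1-sigma errors.
#' @param gamma_int,gamma_int_err internal HWHMs (micro-eV) and errors
#'   (optional: set to NULL to skip the jump fit).
#' @param a fixed methyl H-H distance (Angstrom).
#' @param start list of starting values.
#' @return list with \code{eisf} (estimates p, phi_mobile, R with
#'   1-sigma errors and chi2_nu) and \code{jump} (D_int, tau likewise),
#'   each NULL when the corresponding input is NULL.
#' @export
fit_internal_dynamics <- function(q, A0 = NULL, A0_err = NULL,
                                  gamma_int = NULL, gamma_int_err = NULL,
                                  a = 1.715,
                                  start = list(p = 0.5, phi_mobile = 0.3,
                                               R = 8, D_int = 80,
                                               tau = 0.15)) {
  out <- list(eisf = NULL, jump = NULL)
  logit <- function(x) log(x / (1 - x))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  if (!is.null(A0)) {
    if (length(q) < 4) stop("need at least 4 q points for the EISF fit")
    w <- 1 / pmax(A0_err, 1e-6)^2
    obj <- function(th) {
      p <- inv_logit(th[1]); phi <- inv_logit(th[2]); R <- exp(th[3])
      sum(w * (A0 - eisf_model(q, p, phi, R, a))^2)
    }
    o <- stats::optim(c(logit(start$p), logit(start$phi_mobile),
                        log(start$R)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
    se <- sigma_errors_fd(obj, o$par, h = 1e-3)
    p <- inv_logit(o$par[1]); phi <- inv_logit(o$par[2]); R <- exp(o$par[3])
    out$eisf <- data.frame(
      parameter = c("p", "phi_mobile", "R"),
      estimate = c(p, phi, R),
      se = c(se[1] * p * (1 - p), se[2] * phi * (1 - phi), se[3] * R),
      row.names = NULL)
    attr(out$eisf, "chi2_nu") <- o$value / (length(q) - 3)
  }
  if (!is.null(gamma_int)) {
    if (length(q) < 3) stop("need at least 3 q points for the jump fit")
    w <- 1 / pmax(gamma_int_err, 1e-6)^2
    obj <- function(th) {
      sum(w * (gamma_int - jump_width(q, exp(th[1]), exp(th[2])))^2)
    }
    o <- stats::optim(log(c(start$D_int, start$tau)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
    se <- sigma_errors_fd(obj, o$par, h = 1e-3)
    D_int <- exp(o$par[1]); tau <- exp(o$par[2])
    out$jump <- data.frame(parameter = c("D_int", "tau"),
                           estimate = c(D_int, tau),
                           se = c(se[1] * D_int, se[2] * tau),
                           row.names = NULL)
    attr(out$jump, "chi2_nu") <- o$value / (length(q) - 2)
  }
  out
}
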