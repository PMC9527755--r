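## Bidisperse hard-sphere short-time theory chain: dilute-limit
## Stokes-Einstein anchors, composition-dependent normalized
## diffusivities from a pair-coefficient table, apparent diffusion
## coefficients from the rotational+translational line superposition,
## renormalization to the experimental volume-fraction scale, and
## relative deviations from the pure solutions.

#' Stokes-Einstein dilute-limit diffusivities
#'
#' \eqn{D_t^0 = k_B T / (6\pi\eta R_H)} (Angstrom^2/ns) and
#' \eqn{D_r^0 = k_B T / (8\pi\eta R_H^3)} (1/ns).
#'
#' @param species a \code{\link{protein_species}} (uses \code{R_H}).
#' @param T temperature (K).
#' @param viscosity solvent viscosity (mPa s).
#' @return named vector \code{c(D_t0, D_r0)}.
#' @export
stokes_einstein_limits <- function(species, T, viscosity) {
  R_m <- species$R_H * 1e-10
  eta <- viscosity * 1e-3
  D_t0 <- kB_J_per_K * T / (6 * pi * eta * R_m) * 1e11     # m^2/s -> A^2/ns
  D_r0 <- kB_J_per_K * T / (8 * pi * eta * R_m^3) * 1e-9   # 1/s -> 1/ns
  c(D_t0 = D_t0, D_r0 = D_r0)
}

#' D2O viscosity correlation
#'
#' Vogel-Fulcher fit to heavy-water viscosities (1.247, 1.095,
#' 0.969 mPa s at 20, 25, 30 C):
#' \eqn{\eta(T) = 0.017706\, e^{675.4/(T - 134.4)}} mPa s.
#' Valid roughly 275-330 K.
#'
#' @param T temperature (K).
#' @return viscosity in mPa s.
#' @export
d2o_viscosity <- function(T) 0.017706 * exp(675.4 / (T - 134.4))

#' Bidisperse hard-sphere mixture
#'
#' @param radii length-2 vector of hard-sphere radii (Angstrom).
#' @param phi_pair length-2 vector of partial volume fractions
#'   (hydrodynamic scale); the total must stay below random close
#'   packing (0.64).
#' @param T temperature (K).
#' @param viscosity solvent viscosity (mPa s).
#' @return object of class \code{"hard_sphere_mixture"}.
#' @export
hard_sphere_mixture <- function(radii, phi_pair, T = 295,
                                viscosity = d2o_viscosity(295)) {
  if (length(radii) != 2 || any(radii <= 0)) stop("need two positive radii")
  if (length(phi_pair) != 2 || any(phi_pair < 0))
    stop("need two nonnegative partial volume fractions")
  if (sum(phi_pair) >= 0.64)
    stop("total volume fraction must stay below random close packing (0.64)")
  structure(list(radii = radii, phi = phi_pair, T = T,
                 viscosity = viscosity), class = "hard_sphere_mixture")
}

#' Pair-coefficient table for bidisperse short-time diffusivities
#'
#' Loads the coefficient table behind
#' \code{\link{wang_brady_short_time}}.  The normalized short-time
#' self-diffusivity of species i is evaluated as a polynomial in the
#' total volume fraction,
#' \deqn{D_i/D_i^0 = 1 + c_1^{(i)} \phi + c_2 \phi^2,\qquad
#'   c_1^{(i)} = \sum_j x_j\, \alpha(\lambda_{ij}),}
#' with \eqn{x_j} the composition shares \eqn{\phi_j/\phi} and
#' \eqn{\alpha(\lambda)} a pairwise coefficient depending on the size
#' ratio \eqn{\lambda_{ij} = R_j/R_i}, interpolated from the table
#' (separately for translation and rotation).
#'
#' The default file is a SYNTHETIC stand-in (the published
#' Stokesian-dynamics polynomials are not redistributable here),
#' constructed from the known monodisperse virial limits
#' (\eqn{\alpha_t(1) = -1.8315}, \eqn{\alpha_r(1) = -0.631}, quadratic
#' terms +0.88 and -0.726) and the effective-medium limit
#' \eqn{\alpha \to -2.5} for vanishing crowder size; it honours the
#' dilute, equal-radius and ordering limits exactly.
#'
#' @param path CSV path; default the bundled synthetic table.
#' @return list with interpolators \code{alpha_t(lambda)},
#'   \code{alpha_r(lambda)}, quadratic coefficients \code{c2_t},
#'   \code{c2_r}, the fitted ranges \code{lambda_range} and
#'   \code{phi_max}.
#' @export
wb_default_table <- function(path = system.file(
    "extdata", "hs_pair_coefficients_synthetic.csv",
    package = "biqens", mustWork = TRUE)) {
  tab <- utils::read.csv(path, comment.char = "#")
  pt <- tab[tab$term == "pair_t", ]
  pr <- tab[tab$term == "pair_r", ]
  lr <- range(pt$lambda)
  list(
    alpha_t = stats::splinefun(log(pt$lambda), pt$value, method = "natural"),
    alpha_r = stats::splinefun(log(pr$lambda), pr$value, method = "natural"),
    c2_t = tab$value[tab$term == "quad_t"],
    c2_r = tab$value[tab$term == "quad_r"],
    lambda_range = lr,
    phi_max = tab$value[tab$term == "phi_max"])
}

#' Normalized short-time diffusivities of a bidisperse suspension
#'
#' Translational and rotational short-time self-diffusivities of both
#' species, normalized by their dilute limits, from the pair-coefficient
#' polynomial model (see \code{\link{wb_default_table}}).  Returns the
#' monodisperse values when one partial fraction is zero; refuses to
#' extrapolate outside the table's fitted range.
#'
#' @param mixture a \code{\link{hard_sphere_mixture}}.
#' @param table coefficient table from \code{\link{wb_default_table}}.
#' @return data.frame with one row per species: \code{R}, \code{phi},
#'   \code{Dt_ratio}, \code{Dr_ratio}.
#' @export
wang_brady_short_time <- function(mixture, table = wb_default_table()) {
  stopifnot(inherits(mixture, "hard_sphere_mixture"))
  phi <- sum(mixture$phi)
  if (phi > table$phi_max)
    stop("total volume fraction ", format(phi), " outside the table's ",
         "fitted range [0, ", table$phi_max, "]; no extrapolation")
  x <- if (phi > 0) mixture$phi / phi else c(1, 0)
  out <- data.frame(R = mixture$radii, phi = mixture$phi,
                    Dt_ratio = NA_real_, Dr_ratio = NA_real_)
  for (i in 1:2) {
    lam <- mixture$radii / mixture$radii[i]
    if (any(lam[x > 0] < table$lambda_range[1] - 1e-9) ||
        any(lam[x > 0] > table$lambda_range[2] + 1e-9))
      stop("size ratio outside the table's fitted range [",
           table$lambda_range[1], ", ", table$lambda_range[2], "]")
    c1t <- sum(x * table$alpha_t(log(lam)))
    c1r <- sum(x * table$alpha_r(log(lam)))
    out$Dt_ratio[i] <- 1 + c1t * phi + table$c2_t * phi^2
    out$Dr_ratio[i] <- 1 + c1r * phi + table$c2_r * phi^2
  }
  if (any(out$Dt_ratio <= 0.02) || any(out$Dr_ratio <= 0.02))
    stop("volume fraction outside the table's physical range ",
         "(diffusivity ratio collapsed)")
  out
}

## internal: incoherent rotational weights B_l(x) of a uniform rigid
## sphere, x = qR: B_l = (2l+1) * 3 * int_0^1 j_l(x u)^2 u^2 du
sphere_weight <- function(l, x, nodes, wts) {
  z <- x * nodes
  # besselJ underflows (with a warning) for order >> argument; those
  # contributions are genuinely negligible and set to zero
  jl <- suppressWarnings(
    ifelse(z < 1e-8,
           if (l == 0) 1 else 0,
           sqrt(pi / (2 * z)) * besselJ(z, l + 0.5)))
  jl[!is.finite(jl)] <- 0
  (2 * l + 1) * 3 * sum(wts * jl^2 * nodes^2)
}

## internal: Gauss-Legendre nodes/weights on [0, 1]
gauss_legendre_01 <- function(n = 64L) {
  # Golub-Welsch via symmetric tridiagonal eigen-decomposition
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  A <- matrix(0, n, n)
  A[cbind(k, k + 1L)] <- b
  A[cbind(k + 1L, k)] <- b
  e <- eigen(A, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (x[ord] + 1) / 2, wts = w[ord] / 2)
}

#' Apparent diffusion coefficient from translational and rotational
#' diffusion
#'
#' A rigid sphere of radius R with uniformly distributed scatterers and
#' diffusivities (D_t, D_r) produces the composite quasi-elastic line
#' \deqn{S(q,\omega) = \sum_l B_l(qR)\, L(\omega; \Gamma_l),\qquad
#'   \Gamma_l = \hbar (D_t q^2 + l(l+1) D_r),}
#' with uniform-sphere weights \eqn{B_l}.  The apparent diffusion
#' coefficient is the half width at half maximum of this superposition
#' expressed as a Fickian width, \eqn{D(q) = HWHM/(\hbar q^2)}; the mean
#' over the instrument q grid is reported alongside the per-q values.
#'
#' @param D_t translational diffusion coefficient (Angstrom^2/ns).
#' @param D_r rotational diffusion coefficient (1/ns).
#' @param R effective sphere radius (Angstrom).
#' @param q_grid momentum transfers (1/Angstrom).
#' @param tol tail tolerance of the weight series (truncated when the
#'   residual weight drops below it).
#' @param l_max hard cap on the series order.
#' @return list with \code{D} (mean over q) and \code{D_q} (per q).
#' @export
apparent_diffusion <- function(D_t, D_r, R, q_grid, tol = 1e-6,
                               l_max = 400L) {
  stopifnot(D_t > 0, D_r >= 0, R > 0)
  if (D_r == 0) return(list(D = D_t, D_q = rep(D_t, length(q_grid))))
  gl <- gauss_legendre_01(64L)
  D_q <- vapply(q_grid, function(q) {
    x <- q * R
    B <- numeric(0)
    l <- 0L
    repeat {
      B <- c(B, sphere_weight(l, x, gl$nodes, gl$wts))
      if (1 - sum(B) < tol) break
      l <- l + 1L
      if (l > l_max)
        stop("rotational weight series not converged at qR = ",
             format(x), " within l_max = ", l_max)
    }
    ls <- seq_along(B) - 1L
    Gam <- hbar_ueV_ns * (D_t * q^2 + ls * (ls + 1) * D_r)
    S <- function(w) sum(B * Gam / (pi * (Gam^2 + w^2)))
    S0 <- sum(B / (pi * Gam))
    hw <- stats::uniroot(function(w) S(w) - S0 / 2,
                         lower = Gam[1] * 1e-3,
                         upper = max(Gam) * 1e3,
                         tol = 1e-12 * Gam[1])$root
    hw / (hbar_ueV_ns * q^2)
  }, numeric(1))
  list(D = mean(D_q), D_q = D_q)
}

#' Pure-solution diffusion curve
#'
#' Parametrization of the volume-fraction dependence of the apparent
#' short-time self-diffusion coefficient of a single-protein solution,
#' D(phi) on the experimental (dry, c * nu) volume-fraction scale.
#'
#' @param fun function of phi returning D (Angstrom^2/ns).
#' @param phi_range validity range of phi.
#' @param name label.
#' @return object of class \code{"pure_solution_curve"}; call
#'   \code{predict(curve, phi)} to evaluate.
#' @export
pure_solution_curve <- function(fun, phi_range = c(0, 0.3), name = "") {
  stopifnot(is.function(fun))
  if (fun(phi_range[1]) <= 0) stop("D(phi_min) must be positive")
  structure(list(fun = fun, phi_range = phi_range, name = name),
            class = "pure_solution_curve")
}

#' @export
predict.pure_solution_curve <- function(object, phi, ...) {
  if (any(phi < object$phi_range[1] - 1e-12 |
          phi > object$phi_range[2] + 1e-12))
    stop("phi outside the validity range of the pure-solution curve ",
         object$name)
  vapply(phi, object$fun, numeric(1))
}

#' Self-consistent pure-solution curve from the theory chain
#'
#' Builds D(phi) for a single protein by running the hard-sphere chain at
#' the pure composition: phi is converted to the hydrodynamic scale via
#' the species' number density and R_H, the normalized diffusivities are
#' evaluated at that phi_theo, scaled by the Stokes-Einstein limits, and
#' collapsed to an apparent D over the instrument q grid.  Used as the
#' default experimental parametrization in fully synthetic studies,
#' which makes the pure-solution limits of the renormalization exact.
#'
#' @param species a \code{\link{protein_species}}.
#' @param T temperature (K).
#' @param viscosity solvent viscosity (mPa s).
#' @param q_grid instrument momentum transfers (1/Angstrom).
#' @param table pair-coefficient table.
#' @param phi_range validity range on the experimental phi scale.
#' @return a \code{\link{pure_solution_curve}}.
#' @export
pure_curve_from_theory <- function(species, T = 295,
                                   viscosity = d2o_viscosity(295),
                                   q_grid = seq(0.2, 1.9, length.out = 16),
                                   table = wb_default_table(),
                                   phi_range = c(0, 0.3)) {
  ratio <- hydrodynamic_scale_factor(species)
  se <- stokes_einstein_limits(species, T, viscosity)
  fun <- function(phi) {
    phi_theo <- phi * ratio
    mix <- hard_sphere_mixture(c(species$R_H, species$R_H),
                               c(phi_theo, 0), T, viscosity)
    wb <- wang_brady_short_time(mix, table)
    apparent_diffusion(se["D_t0"] * wb$Dt_ratio[1],
                       se["D_r0"] * wb$Dr_ratio[1],
                       species$R_H, q_grid)$D
  }
  pure_solution_curve(fun, phi_range, species$name)
}

#' Hydrodynamic-to-experimental volume-fraction ratio
#'
#' \eqn{\phi_{theo}/\phi = \frac{4}{3}\pi R_H^3 N_A / (M_w \nu)} for a
#' single species: the factor converting the dry-mass volume fraction
#' c * nu into the effective hard-sphere fraction.
#'
#' @param species a \code{\link{protein_species}}.
#' @return dimensionless scalar.
#' @export
hydrodynamic_scale_factor <- function(species) {
  # per (mg/mL): hydrodynamic fraction / (nu fraction)
  v_hyd <- 4 / 3 * pi * species$R_H^3 * N_Avogadro / 1e27 /
    (species$M_w * 1000)                      # per g/L
  v_hyd / (species$nu / 1000)
}

#' Renormalize a theoretical mixture diffusivity to the experimental
#' volume-fraction scale
#'
#' \deqn{D_{theo}(\phi) = \frac{D^i_{theo,mix}(\phi_{theo})}
#'   {D^i_{theo,mono}(\phi_{theo})} \times D^i_{pure}(\phi)}
#' The mixture/monodisperse ratio is evaluated at the same hydrodynamic
#' volume fraction; multiplying by the experimentally determined pure
#' curve transfers it to the experimental scale.  At y = 0 or 1 the
#' ratio is 1 and the pure-solution value is recovered exactly.
#'
#' @param D_theo_mixture apparent D of the species in the mixture
#'   (theory, at phi_theo).
#' @param D_theo_monodisperse apparent D of the same species alone at the
#'   same total phi_theo.
#' @param pure_curve a \code{\link{pure_solution_curve}}.
#' @param phi_experimental experimental volume fraction.
#' @return renormalized D (Angstrom^2/ns).
#' @export
renormalize_to_experiment <- function(D_theo_mixture, D_theo_monodisperse,
                                      pure_curve, phi_experimental) {
  (D_theo_mixture / D_theo_monodisperse) *
    predict(pure_curve, phi_experimental)
}

#' Single-Lorentzian average of two weighted Lorentzians
#'
#' The width of the single Lorentzian that best approximates (least
#' squares on the resolution-free line shape, amplitude free) the
#' weighted sum of two Lorentzians with widths proportional to D_1 and
#' D_2.  Because all widths share the factor \eqn{\hbar q^2} the result
#' is q-independent and is computed directly on the D scale.  For
#' 0 < s < 1 the average lies strictly between the two inputs.
#'
#' @param D1,D2 component diffusion coefficients (Angstrom^2/ns).
#' @param s1,s2 component weights (sum to 1).
#' @return averaged D (Angstrom^2/ns).
#' @export
average_theory_diffusion <- function(D1, D2, s1, s2) {
  stopifnot(abs(s1 + s2 - 1) < 1e-8, D1 > 0, D2 > 0)
  if (s1 == 1) return(D1)
  if (s2 == 1) return(D2)
  if (abs(D1 - D2) < 1e-14) return(D1)
  # least-squares overlap: maximize g(D) = D * (sum_i s_i/(D_i + D))^2
  g <- function(D) -D * (s1 / (D1 + D) + s2 / (D2 + D))^2
  stats::optimize(g, interval = range(c(D1, D2)), tol = 1e-12)$minimum
}

#' Relative deviation from the pure-solution curve
#'
#' \eqn{\Delta_i = (D^i - D^i_{pure}(\phi)) / D^i_{pure}(\phi)}, in
#' percent: the central observable of the mixture analysis (positive for
#' the small species, negative for the large one).
#'
#' @param D measured or theoretical apparent D (Angstrom^2/ns).
#' @param pure_curve a \code{\link{pure_solution_curve}}.
#' @param phi experimental volume fraction.
#' @return percent deviation.
#' @export
relative_deviation <- function(D, pure_curve, phi) {
  Dp <- predict(pure_curve, phi)
  100 * (D - Dp) / Dp
}

#' Full theory chain for one sample
#'
#' Runs the bidisperse hard-sphere chain for a sample composition:
#' hydrodynamic volume fractions, normalized diffusivities of both
#' species in the mixture and in their monodisperse references at the
#' same total hydrodynamic fraction, apparent diffusion coefficients,
#' renormalization to the experimental phi, the single-Lorentzian
#' average, and relative deviations.
#'
#' @param composition a \code{\link{sample_composition}}.
#' @param bsa,ig \code{\link{protein_species}}.
#' @param q_grid instrument momentum transfers.
#' @param viscosity solvent viscosity (mPa s); default from
#'   \code{\link{d2o_viscosity}} at the sample temperature.
#' @param table pair-coefficient table.
#' @param pure_bsa,pure_ig \code{\link{pure_solution_curve}}s; defaults
#'   are the self-consistent theory curves.
#' @return a one-row data.frame: phi, y, phi_theo, D_theo per species
#'   (hydrodynamic scale), renormalized D_theo(phi), averaged D, relative
#'   deviations (percent).
#' @export
theory_for_sample <- function(composition, bsa = bsa_species(),
                              ig = ig_species(),
                              q_grid = seq(0.2, 1.9, length.out = 16),
                              viscosity = NULL,
                              table = wb_default_table(),
                              pure_bsa = NULL, pure_ig = NULL) {
  if (is.null(viscosity)) viscosity <- d2o_viscosity(composition$T)
  vf <- volume_fractions(composition, bsa, ig)
  tvf <- theory_volume_fraction(composition, bsa, ig)
  if (is.null(pure_bsa))
    pure_bsa <- pure_curve_from_theory(bsa, composition$T, viscosity,
                                       q_grid, table,
                                       phi_range = c(0, max(0.3, vf["phi"])))
  if (is.null(pure_ig))
    pure_ig <- pure_curve_from_theory(ig, composition$T, viscosity,
                                      q_grid, table,
                                      phi_range = c(0, max(0.3, vf["phi"])))
  mix <- hard_sphere_mixture(c(bsa$R_H, ig$R_H),
                             c(tvf[["phi_BSA"]], tvf[["phi_Ig"]]),
                             composition$T, viscosity)
  wb <- wang_brady_short_time(mix, table)
  seB <- stokes_einstein_limits(bsa, composition$T, viscosity)
  seI <- stokes_einstein_limits(ig, composition$T, viscosity)
  D_mix_B <- apparent_diffusion(seB["D_t0"] * wb$Dt_ratio[1],
                                seB["D_r0"] * wb$Dr_ratio[1],
                                bsa$R_H, q_grid)$D
  D_mix_I <- apparent_diffusion(seI["D_t0"] * wb$Dt_ratio[2],
                                seI["D_r0"] * wb$Dr_ratio[2],
                                ig$R_H, q_grid)$D
  phi_theo <- tvf[["phi_theo"]]
  mono_of <- function(sp, se) {
    m <- hard_sphere_mixture(c(sp$R_H, sp$R_H), c(phi_theo, 0),
                             composition$T, viscosity)
    w <- wang_brady_short_time(m, table)
    apparent_diffusion(se["D_t0"] * w$Dt_ratio[1],
                       se["D_r0"] * w$Dr_ratio[1], sp$R_H, q_grid)$D
  }
  D_mono_B <- mono_of(bsa, seB)
  D_mono_I <- mono_of(ig, seI)
  D_theo_B <- renormalize_to_experiment(D_mix_B, D_mono_B, pure_bsa,
                                        vf[["phi"]])
  D_theo_I <- renormalize_to_experiment(D_mix_I, D_mono_I, pure_ig,
                                        vf[["phi"]])
  w <- incoherent_weights(composition, bsa, ig)
  D_theo_av <- average_theory_diffusion(D_theo_B, D_theo_I,
                                        w[["s_BSA"]], w[["s_Ig"]])
  data.frame(
    phi = vf[["phi"]], y = vf[["y"]], phi_theo = phi_theo,
    D_mix_BSA_hyd = D_mix_B, D_mix_Ig_hyd = D_mix_I,
    D_mono_BSA_hyd = D_mono_B, D_mono_Ig_hyd = D_mono_I,
    D_theo_BSA = D_theo_B, D_theo_Ig = D_theo_I, D_theo_av = D_theo_av,
    delta_BSA_pct = relative_deviation(D_theo_B, pure_bsa, vf[["phi"]]),
    delta_Ig_pct = relative_deviation(D_theo_I, pure_ig, vf[["phi"]]))
}
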