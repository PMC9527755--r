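## Analytic model components: two-Gaussian resolution, solvent line,
## monodisperse-average and bidisperse protein models, EISF, jump widths.

#' Two-Gaussian instrument resolution model
#'
#' Vanadium spectra of backscattering instruments are well described, per
#' momentum transfer, by a sum of two zero-centred Gaussians (a sharp core
#' and a broader pedestal).  Amplitudes are stored as area fractions
#' summing to 1 at each q.
#'
#' @param q momentum transfers (1/Angstrom).
#' @param amp1,amp2 component area weights (>= 0, recycled); normalised to
#'   sum to one per q.
#' @param sigma1,sigma2 component standard deviations (micro-eV, > 0,
#'   recycled).
#' @return object of class \code{"resolution_model"}.
#' @export
resolution_model <- function(q, amp1, sigma1, amp2, sigma2) {
  n <- length(q)
  amp1 <- rep_len(amp1, n); amp2 <- rep_len(amp2, n)
  sigma1 <- rep_len(sigma1, n); sigma2 <- rep_len(sigma2, n)
  bad <- which(sigma1 <= 0 | sigma2 <= 0)
  if (length(bad))
    stop("non-positive resolution width at q index ", paste(bad, collapse = ", "))
  if (any(amp1 < 0 | amp2 < 0)) stop("resolution amplitudes must be >= 0")
  tot <- amp1 + amp2
  if (any(tot <= 0)) stop("resolution amplitudes sum to zero at some q")
  structure(list(q = as.numeric(q),
                 pars = cbind(amp1 = amp1 / tot, sigma1 = sigma1,
                              amp2 = amp2 / tot, sigma2 = sigma2)),
            class = "resolution_model")
}

#' @export
print.resolution_model <- function(x, ...) {
  cat("<resolution_model> two Gaussians at", length(x$q), "q values;",
      "sigma1 range", format(range(x$pars[, "sigma1"]), digits = 3),
      "ueV\n")
  invisible(x)
}

## internal: row index of a q value in a per-q model
q_index <- function(model, q, what = "model") {
  i <- which(abs(model$q - q) < 1e-9)
  if (length(i) != 1)
    stop("q = ", q, " not present in ", what)
  i
}

#' D2O solvent model
#'
#' Per-q amplitude and Lorentzian width of the (broad) solvent
#' quasi-elastic line.  The width defaults to the Fickian width of D2O
#' self-diffusion, \eqn{\gamma = \hbar D q^2}; amplitudes are in expected
#' counts per unit omega area.
#'
#' @param q momentum transfers (1/Angstrom).
#' @param amplitude per-q line areas (counts x micro-eV^-1 scale, >= 0).
#' @param gamma per-q Lorentzian HWHM (micro-eV, > 0).
#' @return object of class \code{"solvent_model"}.
#' @export
solvent_model <- function(q, amplitude, gamma) {
  n <- length(q)
  amplitude <- rep_len(amplitude, n); gamma <- rep_len(gamma, n)
  if (any(gamma <= 0)) stop("solvent widths must be > 0")
  if (any(amplitude < 0)) stop("solvent amplitudes must be >= 0")
  structure(list(q = as.numeric(q), amplitude = amplitude, gamma = gamma),
            class = "solvent_model")
}

#' Default D2O solvent widths
#'
#' Fickian width of heavy-water self-diffusion,
#' \eqn{\gamma(q) = \hbar D_{D2O} q^2} with
#' \eqn{D_{D2O} = 187} Angstrom^2/ns at 295 K.
#'
#' @param q momentum transfers (1/Angstrom).
#' @param D_D2O self-diffusion coefficient of D2O (Angstrom^2/ns).
#' @return widths in micro-eV.
#' @export
d2o_width <- function(q, D_D2O = 187) hbar_ueV_ns * D_D2O * q^2

#' Convolve model components with the instrument resolution
#'
#' Each quasi-elastic Lorentzian convolved with a Gaussian resolution
#' component is a Voigt profile, evaluated analytically via the complex
#' error function; purely elastic (delta) components become the resolution
#' shape itself.
#'
#' @param components list of terms; each term is a list with fields
#'   \code{type} (\code{"lorentzian"} or \code{"elastic"}), \code{weight}
#'   (area), and for Lorentzians \code{gamma} (HWHM, micro-eV).
#' @param resolution a \code{\link{resolution_model}}.
#' @param q the momentum transfer (must be present in \code{resolution}).
#' @param omega_grid energy transfers (micro-eV).
#' @return intensity density on \code{omega_grid} (area = sum of weights).
#' @export
convolve_with_resolution <- function(components, resolution, q, omega_grid) {
  i <- q_index(resolution, q, "resolution model")
  p <- resolution$pars[i, ]
  out <- numeric(length(omega_grid))
  for (term in components) {
    w <- term$weight
    if (w == 0) next
    if (identical(term$type, "elastic")) {
      out <- out + w * (p["amp1"] * dnorm(omega_grid, sd = p["sigma1"]) +
                        p["amp2"] * dnorm(omega_grid, sd = p["sigma2"]))
    } else if (identical(term$type, "lorentzian")) {
      if (term$gamma <= 0) stop("Lorentzian component requires gamma > 0")
      out <- out +
        w * (p["amp1"] * voigt_profile(omega_grid, p["sigma1"], term$gamma) +
             p["amp2"] * voigt_profile(omega_grid, p["sigma2"], term$gamma))
    } else stop("unknown component type: ", term$type)
  }
  out
}

## internal: per-q solvent term already convolved with the resolution
solvent_term <- function(solvent, resolution, q, omega_grid) {
  i <- q_index(solvent, q, "solvent model")
  convolve_with_resolution(
    list(list(type = "lorentzian", weight = solvent$amplitude[i],
              gamma = solvent$gamma[i])),
    resolution, q, omega_grid)
}

#' Monodisperse-average spectral model
#'
#' The simplified per-q model for a protein solution: one Lorentzian for
#' the (averaged) global centre-of-mass diffusion and one for the internal
#' diffusive processes, weighted by the elastic incoherent structure
#' factor \code{A0}, convolved with the resolution and summed with the
#' solvent line:
#' \deqn{S = R \otimes \{\beta [A_0 L(\gamma_{glob}) +
#'   (1-A_0) L(\gamma_{tot})] + solvent\}}
#' In the default \code{internal_width_mode = "additive"} the internal
#' line rides on the global process, \eqn{\gamma_{tot} = \gamma_{glob} +
#' \gamma_{int}} (Lorentzian widths add under convolution); in
#' \code{"standalone"} mode \eqn{\gamma_{tot} = \gamma_{int}} and
#' \eqn{\gamma_{int} > \gamma_{glob}} is required.
#'
#' @param beta overall protein amplitude (area, >= 0).
#' @param gamma_glob global-diffusion HWHM (micro-eV).
#' @param gamma_int internal-dynamics HWHM (micro-eV).
#' @param A0 elastic incoherent structure factor in \[0, 1\].
#' @param solvent a \code{\link{solvent_model}}.
#' @param resolution a \code{\link{resolution_model}}.
#' @param q momentum transfer (1/Angstrom).
#' @param omega_grid energy transfers (micro-eV).
#' @param internal_width_mode \code{"additive"} or \code{"standalone"}.
#' @return intensity density on \code{omega_grid}.
#' @export
mono_model <- function(beta, gamma_glob, gamma_int, A0, solvent, resolution,
                       q, omega_grid, internal_width_mode = "additive") {
  if (A0 < 0 || A0 > 1) stop("A0 must lie in [0, 1]")
  if (gamma_glob <= 0 || gamma_int <= 0) stop("widths must be > 0")
  mode <- match.arg(internal_width_mode, c("additive", "standalone"))
  gamma_tot <- if (mode == "additive") gamma_glob + gamma_int else gamma_int
  if (mode == "standalone" && gamma_int <= gamma_glob)
    stop("internal width must exceed the global width (gamma_int <= gamma_glob)")
  prot <- list(
    list(type = "lorentzian", weight = beta * A0, gamma = gamma_glob),
    list(type = "lorentzian", weight = beta * (1 - A0), gamma = gamma_tot))
  convolve_with_resolution(prot, resolution, q, omega_grid) +
    solvent_term(solvent, resolution, q, omega_grid)
}

#' Bidisperse spectral model
#'
#' Two global Lorentzians with widths \eqn{\gamma_i = \hbar D_i q^2},
#' weighted by the incoherent cross-section weights \eqn{s_i}, sharing one
#' internal line and one EISF averaged over both proteins:
#' \deqn{S = R \otimes \{\beta [A_0 (s_{BSA} L(\gamma_{BSA}) +
#'   s_{Ig} L(\gamma_{Ig})) + (1-A_0) L(\gamma_{tot})] + solvent\}}
#' The internal width must exceed the width of the broader global line;
#' in the default additive mode \eqn{\gamma_{tot} = \max(\gamma_{BSA},
#' \gamma_{Ig}) + \gamma_{int}}, which guarantees this.  The evaluation
#' is symmetric under relabelling (swapping the (weight, D) pairs); the
#' ordering convention \code{D_Ig < D_BSA} is an identifiability
#' constraint enforced at the fitting stage, not here.
#'
#' @param D_BSA,D_Ig apparent diffusion coefficients (Angstrom^2/ns).
#' @param s_BSA,s_Ig incoherent weights, summing to 1.
#' @param beta protein amplitude (area, >= 0).
#' @param A0 averaged EISF in \[0, 1\].
#' @param gamma_int internal HWHM (micro-eV).
#' @inheritParams mono_model
#' @return intensity density on \code{omega_grid}.
#' @export
bidisperse_model <- function(D_BSA, D_Ig, s_BSA, s_Ig, beta, A0, gamma_int,
                             solvent, resolution, q, omega_grid,
                             internal_width_mode = "additive") {
  if (abs(s_BSA + s_Ig - 1) > 1e-8) stop("weights s_BSA + s_Ig must equal 1")
  if (A0 < 0 || A0 > 1) stop("A0 must lie in [0, 1]")
  if (D_BSA <= 0 || D_Ig <= 0) stop("diffusion coefficients must be > 0")
  g_bsa <- hbar_ueV_ns * D_BSA * q^2
  g_ig <- hbar_ueV_ns * D_Ig * q^2
  g_base <- max(g_bsa, g_ig)
  mode <- match.arg(internal_width_mode, c("additive", "standalone"))
  gamma_tot <- if (mode == "additive") g_base + gamma_int else gamma_int
  if (gamma_tot <= g_base)
    stop("constraint violated: internal width must exceed the broader ",
         "global width")
  prot <- list(
    list(type = "lorentzian", weight = beta * A0 * s_BSA, gamma = g_bsa),
    list(type = "lorentzian", weight = beta * A0 * s_Ig, gamma = g_ig),
    list(type = "lorentzian", weight = beta * (1 - A0), gamma = gamma_tot))
  convolve_with_resolution(prot, resolution, q, omega_grid) +
    solvent_term(solvent, resolution, q, omega_grid)
}

#' EISF model: immobile fraction, methyl jumps and diffusion in a sphere
#'
#' \deqn{A_0(q) = p + (1-p)[\phi E_{methyl}(q;a) +
#'   (1-\phi) E_{sphere}(q;R)]}
#' with the three-site-jump methyl EISF
#' \eqn{E_{methyl} = \frac{1}{3}(1 + 2 j_0(qa))} and the
#' diffusion-in-a-sphere EISF \eqn{E_{sphere} = (3 j_1(qR)/(qR))^2};
#' \eqn{j_0, j_1} are spherical Bessel functions and
#' \eqn{a = 1.715} Angstrom the mean methyl H-H distance.
#'
#' @param q momentum transfers (1/Angstrom).
#' @param p immobile fraction in \[0, 1\].
#' @param phi_mobile methyl-like fraction of the mobile hydrogens, \[0, 1\].
#' @param R confinement radius (Angstrom, > 0).
#' @param a methyl H-H distance (Angstrom), fixed at 1.715 by default.
#' @return \code{A0(q)}, with \code{A0(0) = 1}.
#' @export
eisf_model <- function(q, p, phi_mobile, R, a = 1.715) {
  if (p < 0 || p > 1 || phi_mobile < 0 || phi_mobile > 1)
    stop("p and phi_mobile must lie in [0, 1]")
  if (R <= 0 || a <= 0) stop("R and a must be > 0")
  j0 <- function(x) ifelse(x == 0, 1, sin(x) / x)
  j1_over_x <- function(x)
    ifelse(x < 1e-6, 1 / 3 - x^2 / 30, (sin(x) / x^2 - cos(x) / x) / x)
  e_methyl <- (1 + 2 * j0(q * a)) / 3
  e_sphere <- (3 * j1_over_x(q * R))^2
  p + (1 - p) * (phi_mobile * e_methyl + (1 - phi_mobile) * e_sphere)
}

#' Jump-diffusion width law
#'
#' HWHM of diffusion with residence time \code{tau} between jumps:
#' \deqn{\gamma(q) = \frac{\hbar D_{int} q^2}{1 + D_{int} q^2 \tau}}
#' Fickian (\eqn{\hbar D q^2}) at small q, saturating at \eqn{\hbar/\tau}.
#'
#' @param q momentum transfers (1/Angstrom).
#' @param D_int internal diffusion coefficient (Angstrom^2/ns, > 0).
#' @param tau residence time (ns, > 0).
#' @return widths in micro-eV.
#' @export
jump_width <- function(q, D_int, tau) {
  if (D_int <= 0 || tau <= 0) stop("D_int and tau must be > 0")
  hbar_ueV_ns * D_int * q^2 / (1 + D_int * q^2 * tau)
}
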