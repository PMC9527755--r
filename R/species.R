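## Sample-composition bookkeeping: cross-section weights, volume
## fractions, mixing ratio — the x-axes of the diffusion/volume-fraction
## plots and the spectral weights of the bidisperse model.

#' Protein species parameters
#'
#' @param name label, e.g. \code{"BSA"}.
#' @param M_w molar mass (kDa).
#' @param sigma_inc incoherent neutron cross section per molecule (barn).
#' @param nu partial specific volume (mL/g).
#' @param R_H effective hydrodynamic radius (Angstrom).
#' @return object of class \code{"protein_species"}.
#' @export
protein_species <- function(name, M_w, sigma_inc, nu, R_H) {
  vals <- c(M_w = M_w, sigma_inc = sigma_inc, nu = nu, R_H = R_H)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all numeric species fields must be positive")
  structure(list(name = name, M_w = M_w, sigma_inc = sigma_inc,
                 nu = nu, R_H = R_H), class = "protein_species")
}

#' Default species: bovine serum albumin and polyclonal immunoglobulin
#'
#' Literature constants used as pipeline defaults: molar masses 66.4 and
#' 150 kDa, partial specific volumes 0.735 and 0.739 mL/g, per-molecule
#' incoherent cross sections 464377.95 and 1011495.41 barn (computed by
#' the original study from PDB entries 4F5S and 1IGT), and effective
#' hard-sphere hydrodynamic radii of 33 and 45 Angstrom (slightly above
#' the dry-volume radii of 27 and 35 Angstrom; the theory chain
#' renormalizes away the absolute radius scale).
#'
#' @return a \code{protein_species}.
#' @export
bsa_species <- function() {
  protein_species("BSA", M_w = 66.4, sigma_inc = 464377.95,
                  nu = 0.735, R_H = 33)
}

#' @rdname bsa_species
#' @export
ig_species <- function() {
  protein_species("Ig", M_w = 150, sigma_inc = 1011495.41,
                  nu = 0.739, R_H = 45)
}

#' Sample composition
#'
#' @param c_BSA,c_Ig protein concentrations (mg/mL, >= 0).
#' @param T temperature (K).
#' @return object of class \code{"sample_composition"}.
#' @export
sample_composition <- function(c_BSA, c_Ig, T = 295) {
  if (c_BSA < 0 || c_Ig < 0) stop("concentrations must be >= 0")
  if (T <= 0) stop("temperature must be positive")
  structure(list(c_BSA = c_BSA, c_Ig = c_Ig, T = T),
            class = "sample_composition")
}

## internal: molar concentration (mol/L) from mg/mL and kDa
molar_concentration <- function(c_mg_ml, M_w_kDa) c_mg_ml / (M_w_kDa * 1000)

#' Incoherent cross-section weights of the two proteins
#'
#' The spectral weight of each protein is proportional to its molar
#' concentration times its per-molecule incoherent cross section:
#' \deqn{s_i = \frac{c_i \sigma_i}{c_{BSA}\sigma_{BSA} +
#'   c_{Ig}\sigma_{Ig}}}
#' (molar concentrations).  Weights sum to one and are invariant under
#' uniform dilution.
#'
#' @param composition a \code{\link{sample_composition}}.
#' @param bsa,ig \code{\link{protein_species}} for the two components.
#' @return named vector \code{c(s_BSA =, s_Ig =)}.
#' @export
incoherent_weights <- function(composition, bsa = bsa_species(),
                               ig = ig_species()) {
  if (composition$c_BSA == 0 && composition$c_Ig == 0)
    stop("weights undefined: both concentrations are zero")
  wB <- molar_concentration(composition$c_BSA, bsa$M_w) * bsa$sigma_inc
  wI <- molar_concentration(composition$c_Ig, ig$M_w) * ig$sigma_inc
  c(s_BSA = wB, s_Ig = wI) / (wB + wI)
}

#' Volume fractions and mixing ratio
#'
#' Experimental (dry mass) volume fractions \eqn{\phi_i = c_i \nu_i}, the
#' total \eqn{\phi = \phi_{BSA} + \phi_{Ig}}, and the mixing ratio
#' \eqn{y = \phi_{BSA}/\phi}.
#'
#' @inheritParams incoherent_weights
#' @return named vector \code{c(phi_BSA, phi_Ig, phi, y)}.
#' @export
volume_fractions <- function(composition, bsa = bsa_species(),
                             ig = ig_species()) {
  phiB <- composition$c_BSA / 1000 * bsa$nu  # mg/mL * mL/g -> dimensionless
  phiI <- composition$c_Ig / 1000 * ig$nu
  phi <- phiB + phiI
  if (phi == 0) stop("mixing ratio undefined: total volume fraction is zero")
  c(phi_BSA = phiB, phi_Ig = phiI, phi = phi, y = phiB / phi)
}

#' Hydrodynamic (theory) volume fraction
#'
#' Effective hard-sphere volume fraction from number densities:
#' \deqn{\phi_{theo} = \sum_i n_i \frac{4}{3}\pi (R_H^i)^3, \qquad
#'   n_i = \frac{c_i N_A}{M_w^i}}
#'
#' @inheritParams incoherent_weights
#' @return named vector \code{c(phi_BSA, phi_Ig, phi_theo)} on the
#'   hydrodynamic scale.
#' @export
theory_volume_fraction <- function(composition, bsa = bsa_species(),
                                   ig = ig_species()) {
  one <- function(c_mg_ml, sp) {
    if (is.null(sp$R_H) || !is.finite(sp$R_H)) stop("missing R_H for ", sp$name)
    # n in molecules / Angstrom^3: c[g/L] / (M_w[g/mol]) * N_A / (1e27 A^3/L)
    n <- c_mg_ml / (sp$M_w * 1000) * N_Avogadro / 1e27
    n * 4 / 3 * pi * sp$R_H^3
  }
  pB <- one(composition$c_BSA, bsa)
  pI <- one(composition$c_Ig, ig)
  c(phi_BSA = pB, phi_Ig = pI, phi_theo = pB + pI)
}
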