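## Faddeeva function and Voigt profile.
##
## The narrow IN16B-like resolution (sigma ~ 0.4 ueV) convolved with
## quasi-elastic Lorentzians is evaluated analytically as a Voigt profile
## via the complex error function w(z) = exp(-z^2) erfc(-iz); no installed
## R package provides w(z), so it is implemented here (Weideman's rational
## approximation, switched to a Laplace continued fraction far from the
## origin).  The FFT convolution path lives in the tests as the oracle.

# Weideman (1994) coefficients, computed once at load time. N = 64 gives
# ~1e-13 relative accuracy in the upper half plane near the real axis.
.weideman_env <- new.env(parent = emptyenv())

weideman_coefficients <- function(N = 64L) {
  key <- as.character(N)
  if (!is.null(.weideman_env[[key]])) return(.weideman_env[[key]])
  M <- 2L * N
  M2 <- 2L * M
  k <- seq(-M + 1L, M - 1L)
  L <- sqrt(N / sqrt(2))
  theta <- k * pi / M
  t <- L * tan(theta / 2)
  f <- exp(-t^2) * (L^2 + t^2)
  f <- c(0, f)
  # polynomial coefficients via FFT on the unit circle
  a <- Re(fft(f[c((M + 1L):M2, 1L:M)])) / M2
  a <- rev(a[2:(N + 1)])
  res <- list(a = a, L = L)
  .weideman_env[[key]] <- res
  res
}

#' Faddeeva function w(z) for Im(z) >= 0
#'
#' Scaled complex complementary error function
#' \eqn{w(z) = e^{-z^2}\,\mathrm{erfc}(-iz)}, the workhorse behind the
#' Voigt profile.  Valid for arguments in the closed upper half plane.
#'
#' @param z complex vector with \code{Im(z) >= 0}.
#' @return complex vector of the same length.
#' @export
faddeeva_w <- function(z) {
  z <- as.complex(z)
  if (any(Im(z) < -1e-12)) stop("faddeeva_w() requires Im(z) >= 0")
  w <- complex(length(z))
  big <- Mod(z) > 8
  if (any(big)) {
    # Laplace continued fraction, accurate to ~1e-14 for |z| > 8
    zz <- z[big]
    t <- zz
    for (an in rev(seq_len(10)) / 2) t <- zz - an / t
    w[big] <- (1i / sqrt(pi)) / t
  }
  if (any(!big)) {
    cf <- weideman_coefficients()
    a <- cf$a; L <- cf$L
    zz <- z[!big]
    iz <- 1i * zz
    Z <- (L + iz) / (L - iz)
    p <- complex(length(zz))
    for (ak in a) p <- p * Z + ak     # Horner, highest order first
    w[!big] <- 2 * p / (L - iz)^2 + (1 / sqrt(pi)) / (L - iz)
  }
  w
}

#' Unit-area Voigt profile
#'
#' Convolution of a unit-area Gaussian (standard deviation \code{sigma})
#' with a unit-area Lorentzian (half width at half maximum \code{gamma}),
#' centred at \code{center}.  Degenerate limits are handled exactly:
#' \code{gamma = 0} returns the Gaussian, \code{sigma = 0} the Lorentzian.
#'
#' @param x evaluation points (micro-eV).
#' @param sigma Gaussian standard deviation (micro-eV), \code{>= 0}.
#' @param gamma Lorentzian HWHM (micro-eV), \code{>= 0}.
#' @param center line centre (micro-eV).
#' @return numeric vector, the profile density (1/micro-eV).
#' @examples
#' omega <- seq(-10, 10, length.out = 201)
#' v <- voigt_profile(omega, sigma = 0.4, gamma = 1.2)
#' @export
voigt_profile <- function(x, sigma, gamma, center = 0) {
  stopifnot(length(sigma) == 1, length(gamma) == 1, sigma >= 0, gamma >= 0)
  x <- x - center
  if (sigma == 0 && gamma == 0)
    stop("voigt_profile() needs sigma > 0 or gamma > 0")
  if (gamma == 0) return(dnorm(x, sd = sigma))
  if (sigma == 0) return(lorentzian(x, gamma))
  z <- (x + 1i * gamma) / (sigma * sqrt(2))
  Re(faddeeva_w(z)) / (sigma * sqrt(2 * pi))
}

## internal: Voigt profiles for several (sigma, gamma) pairs in a single
## Faddeeva evaluation; returns a length(x) x length(sigma) matrix.
## Hot path of the spectral fits.
voigt_multi <- function(x, sigma, gamma) {
  k <- length(sigma)
  n <- length(x)
  denom <- rep(sigma * sqrt(2), each = n)
  z <- complex(real = rep(x, k), imaginary = rep(gamma, each = n)) / denom
  matrix(Re(faddeeva_w(z)) / (denom * sqrt(pi)), n, k)
}

#' Unit-area Lorentzian
#'
#' \eqn{L(\omega;\gamma) = \gamma / (\pi(\gamma^2 + \omega^2))}: the
#' quasi-elastic line of a Fickian diffuser, with HWHM
#' \eqn{\gamma = \hbar D q^2}.
#'
#' @param omega energy transfers (micro-eV).
#' @param gamma HWHM (micro-eV), must be \code{> 0}.
#' @param center line centre (micro-eV).
#' @return numeric vector of densities (1/micro-eV).
#' @export
lorentzian <- function(omega, gamma, center = 0) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("lorentzian() requires a single HWHM gamma > 0")
  x <- omega - center
  (gamma / pi) / (gamma^2 + x^2)
}
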