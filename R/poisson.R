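## Poisson maximum-likelihood building blocks shared by the reduction and
## fitting stages: deviance, identity-link IRLS for nonnegative
## amplitudes, and a weighted pool-adjacent-violators projection.

#' Poisson deviance
#'
#' \eqn{2\sum_k [\mu_k - y_k + y_k \log(y_k/\mu_k)]}, the -2 log-likelihood
#' up to a data-only constant; zero counts contribute \eqn{2\mu_k}.
#'
#' @param y observed counts.
#' @param mu expected counts (> 0; clamped at 1e-12).
#' @return scalar deviance.
#' @export
poisson_deviance <- function(y, mu) {
  mu <- pmax(mu, 1e-12)
  term <- mu - y
  pos <- y > 0
  term[pos] <- term[pos] + y[pos] * log(y[pos] / mu[pos])
  2 * sum(term)
}

## internal: Poisson MLE of mu = offset + F %*% a with a >= 0, identity
## link, small k (1 or 2 columns).  Returns amplitudes, deviance and the
## Fisher information matrix F' W F at the optimum.
irls_amplitudes <- function(y, F, offset = 0, n_iter = 25L) {
  F <- as.matrix(F)
  k <- ncol(F)
  off <- rep_len(offset, length(y))
  # moment start: weighted least squares with w = 1/(y + 1)
  w <- 1 / (y + 1)
  a <- tryCatch({
    M <- crossprod(F * w, F)
    drop(solve(M, crossprod(F * w, y - off)))
  }, error = function(e) rep(sum(pmax(y - off, 0)) / max(colSums(F), 1), k))
  a <- pmax(a, 0)
  active <- rep(FALSE, k)
  for (it in seq_len(n_iter)) {
    mu <- pmax(off + drop(F %*% a), 1e-10)
    w <- 1 / mu
    free <- which(!active)
    if (!length(free)) break
    Ff <- F[, free, drop = FALSE]
    M <- crossprod(Ff * w, Ff)
    rhs <- crossprod(Ff * w, y - off)
    anew <- tryCatch(drop(solve(M, rhs)), error = function(e) a[free])
    # active-set handling of the nonnegativity constraint
    if (any(anew < 0)) {
      neg <- free[anew < 0]
      active[neg] <- TRUE
      a[neg] <- 0
      next
    }
    delta <- max(abs(anew - a[free]) / pmax(a[free], 1e-8))
    a[free] <- anew
    if (delta < 1e-10) break
  }
  mu <- pmax(off + drop(F %*% a), 1e-10)
  info <- crossprod(F / mu, F)
  list(a = a, mu = mu, deviance = poisson_deviance(y, mu), info = info)
}

## internal: weighted pool-adjacent-violators for a non-increasing fit
pava_nonincreasing <- function(x, w = rep(1, length(x))) {
  # isotonic regression on -x gives non-decreasing; invert
  n <- length(x)
  if (n <= 1) return(x)
  y <- -x
  val <- y; wt <- w; idx <- rep(1L, n)
  m <- 0L
  vals <- numeric(n); wts <- numeric(n); cnts <- integer(n)
  for (i in seq_len(n)) {
    m <- m + 1L
    vals[m] <- y[i]; wts[m] <- w[i]; cnts[m] <- 1L
    while (m > 1L && vals[m - 1L] > vals[m]) {
      wtot <- wts[m - 1L] + wts[m]
      vals[m - 1L] <- (wts[m - 1L] * vals[m - 1L] + wts[m] * vals[m]) / wtot
      wts[m - 1L] <- wtot
      cnts[m - 1L] <- cnts[m - 1L] + cnts[m]
      m <- m - 1L
    }
  }
  out <- numeric(n)
  pos <- 1L
  for (j in seq_len(m)) {
    out[pos:(pos + cnts[j] - 1L)] <- vals[j]
    pos <- pos + cnts[j]
  }
  -out
}
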