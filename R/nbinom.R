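#' Negative binomial log-probability in mean/overdispersion form
#'
#' Log probability mass of a count under the negative binomial parameterized
#' by its mean `mu` and an overdispersion parameter `phi` such that
#' `Var(Y) = mu + phi * mu^2`. `phi = 0` is the Poisson limit.
#'
#' @param y Non-negative integer count (vectorized).
#' @param mu Positive expected count (vectorized).
#' @param phi Overdispersion, `phi >= 0`. Scalar.
#' @return Log probability mass, same length as `y`.
#' @examples
#' nb_logpmf(0, mu = 2, phi = 1) # log(1/3)
#' @export
nb_logpmf <- function(y, mu, phi) {
  stopifnot(length(phi) == 1L, is.finite(phi), phi >= 0, all(mu > 0))
  if (any(y < 0) || any(y != round(y))) {
    stop("`y` must contain non-negative integers", call. = FALSE)
  }
  if (phi == 0) {
    return(stats::dpois(y, lambda = mu, log = TRUE))
  }
  stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE)
}

#' Draw negative binomial counts via the gamma-Poisson mixture
#'
#' Counts have mean `mu` and variance `mu + phi * mu^2`; the gamma mixing
#' distribution has shape `1/phi`. `phi = 0` draws Poisson.
#'
#' @inheritParams nb_logpmf
#' @param n Number of draws.
#' @return Integer vector of counts.
#' @export
rnb_mu_phi <- function(n, mu, phi) {
  stopifnot(length(phi) == 1L, phi >= 0)
  if (phi == 0) {
    return(stats::rpois(n, lambda = mu))
  }
  shape <- 1 / phi
  lambda <- stats::rgamma(n, shape = shape, rate = shape) * mu
  stats::rpois(n, lambda = lambda)
}

# Unchecked fast path used inside optimization loops.
nb_ll <- function(y, mu, phi) {
  if (phi == 0) return(stats::dpois(y, lambda = mu, log = TRUE))
  stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE)
}

# Gradient and curvature of the NB log-pmf with respect to eta = log(mu).
# Returns list(g, w) with w = -d2/deta2 >= 0 (used as Newton weights).
nb_eta_derivs <- function(y, mu, phi) {
  if (phi == 0) {
    return(list(g = y - mu, w = mu))
  }
  r <- 1 / phi
  g <- y - mu * (y + r) / (mu + r)
  w <- mu * (y + r) * r / (mu + r)^2
  list(g = g, w = w)
}
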