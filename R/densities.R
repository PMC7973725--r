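# Log-densities for the random-effect structures and the count likelihood.
# All densities are returned up to additive constants that do not involve
# the arguments named in each function's contract.

#' First-order random-walk (RW1) log-density
#'
#' Log-density (up to an additive constant) of a vector of ordered effects
#' \eqn{\gamma_1,\dots,\gamma_T} under an intrinsic first-order random walk
#' with precision \eqn{\tau}:
#' \deqn{\log \pi(\gamma \mid \tau) = \frac{T-1}{2}\log\tau
#'   - \frac{\tau}{2}\sum_{t=1}^{T-1} (\gamma_{t+1}-\gamma_t)^2 + const.}
#' The RW1 is rank-deficient (its level is unidentified); the fitting engine
#' imposes a sum-to-zero constraint on \eqn{\gamma}, and `center = TRUE`
#' evaluates the density at the centred vector for convenience.
#'
#' @param gamma numeric vector of at least two time effects.
#' @param tau precision of the increments, > 0.
#' @param center if TRUE, subtract `mean(gamma)` before evaluating.
#' @return Log-density value (scalar), up to a constant.
#' @export
rw1_logdensity <- function(gamma, tau, center = FALSE) {
  stopifnot(is.numeric(gamma), all(is.finite(gamma)))
  if (length(gamma) < 2L) stop("rw1_logdensity: need at least 2 time points")
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("rw1_logdensity: 'tau' must be a positive scalar")
  if (center) gamma <- gamma - mean(gamma)
  0.5 * (length(gamma) - 1L) * log(tau) - 0.5 * tau * sum(diff(gamma)^2)
}

#' Penalised-complexity prior for a standard deviation
#'
#' The PC prior for the standard deviation of a Gaussian random effect is an
#' exponential density on \eqn{\sigma \ge 0} with rate
#' \eqn{\lambda = -\log(\alpha)/u}, calibrated so that
#' \eqn{P(\sigma > u) = \alpha} exactly.
#'
#' @param sigma standard deviation(s), >= 0.
#' @param u scale of the tail statement, > 0.
#' @param alpha tail probability, in (0, 1).
#' @param log if FALSE return the density itself.
#' @return Log-density (default) or density, vectorised over `sigma`.
#' @export
pc_prior_sd_logdensity <- function(sigma, u, alpha, log = TRUE) {
  if (!is.numeric(u) || length(u) != 1L || u <= 0)
    stop("pc_prior_sd_logdensity: 'u' must be a positive scalar")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("pc_prior_sd_logdensity: 'alpha' must lie strictly in (0, 1)")
  stopifnot(is.numeric(sigma), all(sigma >= 0))
  lambda <- -log(alpha) / u
  ld <- log(lambda) - lambda * sigma
  if (log) ld else exp(ld)
}

#' Penalised-complexity prior for a Matern practical range (2-D)
#'
#' For a two-dimensional Matern field the PC prior on the practical range
#' \eqn{\rho} calibrated by \eqn{P(\rho < u) = \alpha} has density
#' \deqn{\pi(\rho) = \lambda\,\rho^{-2} e^{-\lambda/\rho},\qquad
#'   \lambda = -u \log(\alpha),}
#' an inverse-exponential law whose lower tail mass below `u` is exactly
#' `alpha`.
#'
#' @param rho practical range value(s), > 0.
#' @param u range threshold of the tail statement, > 0.
#' @param alpha probability that the range falls below `u`, in (0, 1).
#' @param log if FALSE return the density itself.
#' @return Log-density (default) or density, vectorised over `rho`.
#' @export
pc_prior_range_logdensity <- function(rho, u, alpha, log = TRUE) {
  if (!is.numeric(u) || length(u) != 1L || u <= 0)
    stop("pc_prior_range_logdensity: 'u' must be a positive scalar")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("pc_prior_range_logdensity: 'alpha' must lie strictly in (0, 1)")
  stopifnot(is.numeric(rho), all(rho > 0))
  lambda <- -u * log(alpha)
  ld <- log(lambda) - 2 * log(rho) - lambda / rho
  if (log) ld else exp(ld)
}

#' Zero-inflated Poisson log-probability mass
#'
#' \deqn{P(Y = y) = \pi_0 1\{y=0\} + (1-\pi_0)\,\mathrm{Poisson}(y;\theta)}
#' A single zero-inflation mass \eqn{\pi_0} applies to all observations;
#' there are no covariates on the zero component.
#'
#' @param y nonnegative integer count(s).
#' @param theta Poisson mean(s), > 0 (or 0 in the degenerate limit).
#' @param pi0 zero-inflation probability in [0, 1).
#' @return Log-probability, vectorised over `y` / `theta`.
#' @examples
#' zip_logpmf(0, theta = 1, pi0 = 0.2)  # log(0.2 + 0.8 * exp(-1))
#' @export
zip_logpmf <- function(y, theta, pi0) {
  stopifnot(is.numeric(y), is.numeric(theta), is.numeric(pi0),
            length(pi0) == 1L)
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y)))
    stop("zip_logpmf: 'y' must contain nonnegative integers")
  if (any(theta < 0)) stop("zip_logpmf: 'theta' must be >= 0")
  if (pi0 < 0 || pi0 >= 1) stop("zip_logpmf: 'pi0' must lie in [0, 1)")
  n <- max(length(y), length(theta))
  y <- rep_len(y, n); theta <- rep_len(theta, n)
  out <- numeric(n)
  zero <- y == 0
  # y = 0: log(pi0 + (1 - pi0) e^-theta), stable via log-sum-exp
  if (any(zero)) {
    a <- log1p(-pi0) - theta[zero]
    if (pi0 > 0) {
      b <- log(pi0)
      m <- pmax(a, b)
      out[zero] <- m + log(exp(a - m) + exp(b - m))
    } else out[zero] <- a
  }
  if (any(!zero))
    out[!zero] <- log1p(-pi0) + stats::dpois(y[!zero], theta[!zero], log = TRUE)
  out
}
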