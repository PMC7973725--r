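#' Matern covariance parameters
#'
#' Container for the three parameters of the stationary Matern covariance
#' family used for the spatially structured random effect: the marginal
#' variance \eqn{\sigma^2}, the inverse-scale \eqn{\kappa > 0} and the
#' smoothness \eqn{\nu > 0}.  The practical range -- the distance at which
#' the spatial correlation has decayed to roughly 0.1 -- is
#' \eqn{\rho = \sqrt{8\nu}/\kappa} and can be recovered with
#' [range_from_kappa()].
#'
#' @param sigma2 marginal variance, > 0.
#' @param kappa inverse scale parameter, > 0 (km^-1 when coordinates are km).
#' @param nu smoothness, > 0.  Defaults to 1, the usual disease-mapping
#'   convention; identifiability of \eqn{\nu} from areal data is weak, so it
#'   is treated as fixed rather than estimated.
#' @return An object of class `matern_params`.
#' @examples
#' p <- matern_params(sigma2 = 1, kappa = 0.5)
#' range_from_kappa(p)
#' @export
matern_params <- function(sigma2, kappa, nu = 1) {
  stopifnot(is.numeric(sigma2), length(sigma2) == 1L, is.finite(sigma2),
            is.numeric(kappa), length(kappa) == 1L, is.finite(kappa),
            is.numeric(nu), length(nu) == 1L, is.finite(nu))
  if (sigma2 <= 0) stop("matern_params: 'sigma2' must be > 0")
  if (kappa <= 0) stop("matern_params: 'kappa' must be > 0")
  if (nu <= 0) stop("matern_params: 'nu' must be > 0")
  structure(list(sigma2 = sigma2, kappa = kappa, nu = nu),
            class = "matern_params")
}

#' @export
print.matern_params <- function(x, ...) {
  cat(sprintf("Matern covariance: sigma2 = %g, kappa = %g, nu = %g (range rho = %g)\n",
              x$sigma2, x$kappa, x$nu, range_from_kappa(x)))
  invisible(x)
}

#' Build Matern parameters from a practical range
#'
#' Convenience inverse of [range_from_kappa()]: given the practical range
#' \eqn{\rho}, returns parameters with \eqn{\kappa = \sqrt{8\nu}/\rho}.
#'
#' @param sigma2 marginal variance, > 0.
#' @param range practical range \eqn{\rho}, > 0.
#' @param nu smoothness, > 0.
#' @return A `matern_params` object.
#' @export
matern_params_from_range <- function(sigma2, range, nu = 1) {
  stopifnot(is.numeric(range), length(range) == 1L, is.finite(range))
  if (range <= 0) stop("matern_params_from_range: 'range' must be > 0")
  matern_params(sigma2 = sigma2, kappa = sqrt(8 * nu) / range, nu = nu)
}

#' Matern covariance function
#'
#' Evaluates
#' \deqn{C(d) = \frac{\sigma^2}{2^{\nu-1}\Gamma(\nu)} (\kappa d)^{\nu}
#'       K_{\nu}(\kappa d)}
#' for distances \eqn{d > 0}, with \eqn{C(0) = \sigma^2} by continuity.
#' \eqn{K_\nu} is the modified Bessel function of the second kind.
#'
#' @param d distance(s), >= 0, same length units as 1/kappa.
#' @param params a [matern_params()] object.
#' @return Covariance value(s), vectorised over `d`.
#' @examples
#' matern_covariance(0, matern_params(2.5, 1))          # 2.5
#' matern_covariance(1, matern_params(1, 1, nu = 0.5))  # exp(-1)
#' @export
matern_covariance <- function(d, params) {
  stopifnot(inherits(params, "matern_params"), is.numeric(d))
  if (any(!is.finite(d)) || any(d < 0))
    stop("matern_covariance: distances must be finite and >= 0")
  s2 <- params$sigma2; kap <- params$kappa; nu <- params$nu
  out <- numeric(length(d))
  zero <- d == 0
  out[zero] <- s2
  if (any(!zero)) {
    kd <- kap * d[!zero]
    # log-scale evaluation; besselK overflows for small kd at large nu
    out[!zero] <- s2 * exp((1 - nu) * log(2) - lgamma(nu) + nu * log(kd) +
                             log(besselK(kd, nu, expon.scaled = TRUE)) - kd)
  }
  out
}

#' Practical range of a Matern covariance
#'
#' Returns \eqn{\rho = \sqrt{8\nu}/\kappa}, the distance at which the Matern
#' correlation is approximately 0.1.
#'
#' @param params a [matern_params()] object.
#' @return The practical range (same units as distance).
#' @export
range_from_kappa <- function(params) {
  stopifnot(inherits(params, "matern_params"))
  sqrt(8 * params$nu) / params$kappa
}

#' Dense Matern covariance matrix for a point set
#'
#' @param coords two-column matrix (or data frame) of planar coordinates.
#' @param params a [matern_params()] object.
#' @return n x n covariance matrix.
#' @export
matern_cov_matrix <- function(coords, params) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, nrow(coords) >= 1L, all(is.finite(coords)))
  d <- as.matrix(stats::dist(coords))
  matrix(matern_covariance(as.vector(d), params), nrow = nrow(coords))
}

#' Simulate a zero-mean Gaussian field with Matern covariance
#'
#' Draws from the exact finite-dimensional distribution by Cholesky
#' factorisation of the dense covariance matrix.  Intended for desk-scale
#' point sets (a few thousand locations); no low-rank or SPDE approximation
#' is involved.
#'
#' @param coords two-column matrix of planar coordinates.
#' @param params a [matern_params()] object.
#' @param seed integer seed; the draw is reproducible given (`coords`,
#'   `params`, `seed`, `n_draws`).
#' @param n_draws number of independent field draws.
#' @param jitter nonnegative nugget added to the diagonal before
#'   factorisation.  Coincident points make the covariance matrix singular;
#'   the default 1e-10 * sigma2 keeps the factorisation stable without
#'   visibly perturbing the field.
#' @return A length-n vector for `n_draws = 1`, else an n x n_draws matrix.
#' @export
sample_matern_field <- function(coords, params, seed = NULL, n_draws = 1L,
                                jitter = 1e-10) {
  coords <- as.matrix(coords)
  stopifnot(inherits(params, "matern_params"), nrow(coords) >= 1L,
            n_draws >= 1L)
  S <- matern_cov_matrix(coords, params)
  n <- nrow(S)
  L <- tryCatch(chol(S + diag(jitter * params$sigma2, n)),
                error = function(e) NULL)
  if (is.null(L)) {
    L <- tryCatch(chol(S + diag(1e-6 * params$sigma2, n)),
                  error = function(e) NULL)
    if (is.null(L))
      stop("sample_matern_field: covariance matrix is numerically not ",
           "positive definite; increase 'jitter' or perturb coincident points")
  }
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n * n_draws), nrow = n)
  out <- crossprod(L, z)
  if (n_draws == 1L) drop(out) else out
}
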