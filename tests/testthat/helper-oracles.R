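# Independent numerical oracles used across the suite.  These deliberately
# avoid the code paths they check.

# Modified Bessel K_nu via its integral representation
# K_nu(x) = int_0^inf exp(-x cosh t) cosh(nu t) dt
bessel_k_quadrature <- function(x, nu) {
  stats::integrate(function(t) exp(-x * cosh(t)) * cosh(nu * t),
                   lower = 0, upper = 30, rel.tol = 1e-12)$value
}

matern_cov_oracle <- function(d, sigma2, kappa, nu) {
  if (d == 0) return(sigma2)
  kd <- kappa * d
  sigma2 / (2^(nu - 1) * gamma(nu)) * kd^nu * bessel_k_quadrature(kd, nu)
}

# Empirical quantile interval (type 7), brute force
empirical_ci95 <- function(x) unname(stats::quantile(x, c(0.025, 0.975)))
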