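test_that("matern_covariance matches closed forms and the quadrature oracle", {
  # variance at zero distance
  expect_equal(matern_covariance(0, matern_params(2.5, 1)), 2.5)
  # nu = 1/2 is the exponential covariance: sigma2 * exp(-kappa d)
  expect_equal(matern_covariance(1, matern_params(1, 1, nu = 0.5)),
               exp(-1), tolerance = 1e-10)
  expect_equal(matern_covariance(c(0.3, 2), matern_params(1.7, 0.8, nu = 0.5)),
               1.7 * exp(-0.8 * c(0.3, 2)), tolerance = 1e-10)
  # general (nu, kappa, d) against an independent Bessel quadrature
  cases <- expand.grid(d = c(0.1, 0.5, 1, 3), nu = c(0.5, 1, 2, 3.5),
                       kappa = c(0.5, 2))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    expect_equal(
      matern_covariance(cs$d, matern_params(2, cs$kappa, nu = cs$nu)),
      matern_cov_oracle(cs$d, 2, cs$kappa, cs$nu),
      tolerance = 1e-8,
      info = sprintf("d=%g nu=%g kappa=%g", cs$d, cs$nu, cs$kappa))
  }
  # frozen value: nu=1, sigma2=2, kappa=2, d=0.5 -> 2 K_1(1)
  expect_equal(matern_covariance(0.5, matern_params(2, 2, nu = 1)),
               1.20381446, tolerance = 1e-7)
  expect_error(matern_covariance(-1, matern_params(1, 1)), ">= 0")
})

test_that("practical range: rho = sqrt(8 nu)/kappa and correlation ~ 0.1 there", {
  expect_equal(range_from_kappa(matern_params(1, 2, nu = 1)), sqrt(8) / 2)
  expect_equal(range_from_kappa(matern_params(1, 1, nu = 0.5)), 2)
  expect_equal(range_from_kappa(matern_params(1, 4, nu = 2)), 1)
  for (nu in c(0.5, 1, 2)) {
    p <- matern_params(1, kappa = 1.3, nu = nu)
    corr_at_range <- matern_covariance(range_from_kappa(p), p)
    expect_gt(corr_at_range, 0.08)
    expect_lt(corr_at_range, 0.16)
  }
  # round trip through matern_params_from_range
  p <- matern_params_from_range(0.5, range = 12, nu = 1)
  expect_equal(range_from_kappa(p), 12, tolerance = 1e-12)
})

test_that("matern_cov_matrix is symmetric positive semi-definite", {
  set.seed(42)
  for (nu in c(0.5, 1, 2)) {
    xy <- matrix(runif(100, 0, 10), ncol = 2)
    S <- matern_cov_matrix(xy, matern_params(1.5, 0.7, nu = nu))
    expect_equal(S, t(S))
    expect_equal(diag(S), rep(1.5, 50))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * 1.5)
  }
})

test_that("sample_matern_field reproduces the target distribution", {
  # single point: marginal is N(0, sigma2)
  p <- matern_params(1, 1)
  draws <- sample_matern_field(matrix(c(0, 0), 1), p, seed = 11,
                               n_draws = 10000)
  expect_equal(stats::var(as.vector(draws)), 1, tolerance = 0.05)
  # coincident points carry identical field values
  xy <- rbind(c(1, 1), c(1, 1), c(3, 4))
  f <- sample_matern_field(xy, p, seed = 2)
  expect_equal(f[1], f[2], tolerance = 1e-4)
  # determinism under a fixed seed
  expect_identical(sample_matern_field(xy, p, seed = 9),
                   sample_matern_field(xy, p, seed = 9))
  # empirical covariance vs closed form, 50 points x 5000 draws,
  # entrywise within 3 Monte Carlo standard errors
  set.seed(7)
  xy <- matrix(runif(100, 0, 8), ncol = 2)
  pp <- matern_params(2, 0.6, nu = 1)
  F <- sample_matern_field(xy, pp, seed = 31, n_draws = 5000)
  S_hat <- tcrossprod(F) / ncol(F)
  S <- matern_cov_matrix(xy, pp)
  # var of a sample covariance entry: (S_ii S_jj + S_ij^2) / n
  mc_se <- sqrt((outer(diag(S), diag(S)) + S^2) / ncol(F))
  z <- abs(S_hat - S) / mc_se
  # with ~1275 distinct entries a handful of >3 SE excursions are expected;
  # demand the 3-SE band holds for virtually all entries and 5 SE for all
  expect_gt(mean(z <= 3), 0.99)
  expect_lt(max(z), 5)
})
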