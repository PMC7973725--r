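# Engine validation against independent oracles on small synthetic data.

make_flat_tracts <- function(n = 100, seed = 1) {
  tr <- generate_landscape(n, seed = seed)
  tr[tr$region == "A", , drop = FALSE]
}

test_that("intercept-only Poisson fit matches the conjugate Gamma oracle", {
  tr <- make_flat_tracts(100, seed = 1)
  trials <- pmax(1, tr$pop_over16)
  set.seed(2)
  y <- rpois(nrow(tr), trials * 6 * exp(-10))
  spec <- two_part_spec(fixed_effects = character(0), selection = FALSE,
                        spatial = FALSE, heterogeneity = FALSE,
                        estimate_pi0 = FALSE, parts = "zip")
  fit <- fit_two_part(tr, y, spec, years = 2013:2018, seed = 3)
  ps <- posterior_summary(fit, "beta:intercept")
  # conjugate oracle: flat-prior posterior of the log rate is
  # log Gamma(sum y, person-years); our prior is N(0, 100), essentially flat
  py <- 6 * sum(trials)
  oracle_mean <- digamma(sum(y)) - log(py)
  oracle_sd <- sqrt(trigamma(sum(y)))
  expect_lt(abs(ps$point - oracle_mean), 3 * oracle_sd)
  expect_lt(abs(ps$point - (-10)), 4 * oracle_sd)
  # interval width agrees with the oracle posterior sd
  expect_equal((ps$upper - ps$lower) / (2 * 1.96), oracle_sd,
               tolerance = 0.15)
  expect_true(fit$converged)
})

test_that("seeded fits are reproducible draw for draw", {
  tr <- make_flat_tracts(60, seed = 5)
  set.seed(6)
  y <- rpois(nrow(tr), pmax(1, tr$pop_over16) * 3e-4)
  spec <- two_part_spec(fixed_effects = c("dep_q2", "dep_q3"),
                        selection = FALSE, spatial = FALSE,
                        heterogeneity = FALSE, estimate_pi0 = TRUE,
                        parts = "zip")
  f1 <- fit_two_part(tr, y, spec, years = 2013, seed = 42)
  f2 <- fit_two_part(tr, y, spec, years = 2013, seed = 42)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_two_part(tr, y, spec, years = 2013, seed = 43)
  expect_false(identical(f1$draws$beta, f3$draws$beta))
})

test_that("decoupled joint fit equals independent single-part fits", {
  tr <- make_flat_tracts(80, seed = 7)
  trials <- pmax(1, tr$pop_over16)
  set.seed(8)
  X <- tract_design(tr)
  lp <- -8 + 0.4 * X[, "dep_q5"]
  y <- rpois(nrow(tr), trials * exp(lp))
  fx <- c("dep_q2", "dep_q3", "dep_q4", "dep_q5")

  joint <- fit_two_part(tr, y, two_part_spec(
    fixed_effects = fx, coupled = FALSE, selection = FALSE,
    spatial = FALSE, heterogeneity = FALSE, estimate_pi0 = FALSE),
    years = 2013, seed = 11)
  only1 <- fit_two_part(tr, y, two_part_spec(
    fixed_effects = fx, coupled = FALSE, selection = FALSE,
    spatial = FALSE, heterogeneity = FALSE, estimate_pi0 = FALSE,
    parts = "binomial"), years = 2013, seed = 12)
  only2 <- fit_two_part(tr, y, two_part_spec(
    fixed_effects = fx, coupled = FALSE, selection = FALSE,
    spatial = FALSE, heterogeneity = FALSE, estimate_pi0 = FALSE,
    parts = "zip"), years = 2013, seed = 13)

  # Monte Carlo error of a posterior median from n draws
  for (nm in c("intercept", "dep_q5")) {
    d_joint <- joint$draws$beta[, nm]
    d_only <- only2$draws$beta[, nm]
    mc <- 1.5 * sd(d_only) * sqrt(2 / length(d_only)) * 5 + 1e-3
    expect_lt(abs(median(d_joint) - median(d_only)), mc)
    d1_joint <- joint$draws$beta1[, nm]
    d1_only <- only1$draws$beta1[, nm]
    mc1 <- 1.5 * sd(d1_only) * sqrt(2 / length(d1_only)) * 5 + 1e-3
    expect_lt(abs(median(d1_joint) - median(d1_only)), mc1)
  }

  # the binomial part alone agrees with a frequentist logistic fit
  gl <- glm(cbind(y, trials - y) ~ X[, fx], family = binomial())
  expect_equal(unname(median(only1$draws$beta1[, "intercept"])),
               unname(coef(gl)[1]), tolerance = 0.02)
  expect_equal(unname(median(only1$draws$beta1[, "dep_q5"])),
               unname(coef(gl)[["X[, fx]dep_q5"]]), tolerance = 0.15)
})

test_that("all-zero counts give a rate posterior concentrated near zero", {
  tr <- make_flat_tracts(60, seed = 9)
  y <- rep(0L, nrow(tr))
  spec <- two_part_spec(fixed_effects = character(0), selection = FALSE,
                        spatial = FALSE, heterogeneity = FALSE,
                        estimate_pi0 = FALSE, parts = "zip")
  fit <- suppressWarnings(fit_two_part(tr, y, spec, years = 2013:2018,
                                       seed = 10))
  est <- region_prevalence(fit)
  # point mass sits at zero; the upper tail reflects genuine no-data
  # uncertainty and stays bounded
  expect_lt(est$point, 0.5)
  expect_lt(est$lower, 0.01)
  expect_lt(est$upper, 100)
})

test_that("posterior_summary gives empirical equal-tailed intervals", {
  # brute-force quantiles of 1..100
  s <- posterior_summary(as.numeric(1:100))
  expect_equal(s$point, 50.5)
  expect_equal(s$lower, 3.475)
  expect_equal(s$upper, 97.525)
  # symmetric draws centred at 3
  set.seed(1)
  d <- 3 + rnorm(20000)
  expect_equal(posterior_summary(d)$point, 3, tolerance = 0.03)
  # monotone transform equivariance
  s2 <- posterior_summary(exp(d))
  expect_equal(s2$lower, exp(posterior_summary(d)$lower), tolerance = 1e-8)
  expect_error(posterior_summary(structure(list(), class = "two_part_fit"),
                                 "nope"), "unknown quantity")
})

test_that("observation_weights needs selection and stays within [0, 1]", {
  tr <- make_flat_tracts(50, seed = 20)
  set.seed(21)
  y <- rpois(nrow(tr), pmax(1, tr$pop_over16) * 2e-4)
  no_sel <- fit_two_part(tr, y, two_part_spec(
    fixed_effects = character(0), selection = FALSE, spatial = FALSE,
    heterogeneity = FALSE, estimate_pi0 = FALSE, parts = "zip"),
    years = 2013, seed = 22)
  expect_error(observation_weights(no_sel), "no part-1")
  # with a selection spec the probabilities are proper and anchored
  sel_fit <- suppressWarnings(fit_two_part(tr, y, two_part_spec(
    fixed_effects = character(0), spatial = FALSE, heterogeneity = FALSE,
    estimate_pi0 = FALSE, endogenous = FALSE), years = 2013, seed = 23))
  ow <- observation_weights(sel_fit)
  expect_true(all(ow$mean >= 0 & ow$mean <= 1))
  expect_true(all(ow$lower <= ow$mean & ow$mean <= ow$upper))
  # a null selection state gives probability 1/2 everywhere
  fake <- structure(list(draws = list(obs_logit = matrix(
    0, 50, nrow(tr), dimnames = list(NULL, tr$tract_id)))),
    class = "two_part_fit")
  expect_true(all(observation_weights(fake)$mean == 0.5))
})
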