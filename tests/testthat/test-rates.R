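# Rate estimation, pooling and descriptive computations.

fake_fit <- function(log_rate_draws, pop, region = "A", target = "prevalence",
                     W = 6, gamma = NULL) {
  structure(list(
    draws = list(log_rate = log_rate_draws, gamma = gamma),
    spec = two_part_spec(target = target, selection = FALSE),
    data = list(tract_id = colnames(log_rate_draws), region = region,
                pop_over16 = pop, pop_total = pop, window_years = W,
                years = seq_len(W), n_tracts = ncol(log_rate_draws))),
    class = "two_part_fit")
}

test_that("region_prevalence is a population-weighted period rate", {
  set.seed(1)
  n <- 4; ndr <- 4000
  pop <- c(1000, 2000, 500, 1500)
  lr <- matrix(rep(log(c(2, 4, 1, 3) / 1e5), each = ndr), ndr, n,
               dimnames = list(NULL, paste0("T", 1:n)))
  fit <- fake_fit(lr, pop, W = 6)
  est <- region_prevalence(fit)
  manual <- 1e5 * 6 * sum(pop * c(2, 4, 1, 3) / 1e5) / sum(pop)
  expect_equal(est$point, manual, tolerance = 1e-10)
  expect_equal(est$lower, est$point)   # degenerate draws
  # splitting one tract into two with halved population leaves it unchanged
  pop2 <- c(500, 500, pop[-1])
  lr2 <- cbind(lr[, 1, drop = FALSE], lr)
  colnames(lr2) <- paste0("T", 0:n)
  expect_equal(region_prevalence(fake_fit(lr2, pop2, W = 6))$point,
               est$point, tolerance = 1e-10)
  # degenerate rate posterior at zero
  lr0 <- matrix(-1e10, 100, n, dimnames = list(NULL, paste0("T", 1:n)))
  e0 <- region_prevalence(fake_fit(lr0, pop))
  expect_equal(c(e0$point, e0$lower, e0$upper), c(0, 0, 0))
  expect_error(region_prevalence(fake_fit(lr, pop, target = "incidence")),
               "target")
})

test_that("region_incidence divides by person-years and averages RW1", {
  n <- 3; ndr <- 500
  pop <- c(4e5, 3e5, 3e5)   # 1e6 at risk
  # 10 expected cases a year over 1e6 person-years: 1.0 per 100,000 py
  lr <- matrix(rep(log(10 / 1e6), ndr * n), ndr, n,
               dimnames = list(NULL, paste0("T", 1:n)))
  gam <- matrix(0, ndr, 4)
  fit <- fake_fit(lr, pop, target = "incidence", W = 4, gamma = gam)
  est <- region_incidence(fit)
  expect_equal(est$point, 1.0, tolerance = 1e-10)
  # doubling the period with constant rates leaves the rate unchanged
  fit8 <- fake_fit(lr, pop, target = "incidence", W = 8,
                   gamma = matrix(0, ndr, 8))
  expect_equal(region_incidence(fit8)$point, 1.0, tolerance = 1e-10)
  expect_error(region_incidence(fit, period = integer()), "empty period")
})

test_that("tract_rates flags small tracts and aggregates consistently", {
  set.seed(3)
  n <- 40; ndr <- 3000
  pop <- c(rep(30, 5), round(runif(n - 5, 500, 3000)))
  lr <- matrix(log(2e-5) + rnorm(ndr * n, 0, 0.1), ndr, n,
               dimnames = list(NULL, paste0("T", 1:n)))
  fit <- fake_fit(lr, pop, W = 1)
  trr <- tract_rates(fit, pop_floor = 50)
  expect_equal(sum(trr$unstable), 5)
  expect_setequal(trr$scope[trr$unstable], paste0("T", 1:5))
  expect_true(all(trr$lower <= trr$point & trr$point <= trr$upper))
  # population-weighted mean of tract rates ~ region rate within MC error
  reg <- region_prevalence(fit)
  expect_equal(weighted.mean(trr$point, pop), reg$point, tolerance = 0.02)
})

test_that("pool_intervals reproduces the published pooled bounds", {
  va <- list(measure = "prevalence", category = "MND",
             lower = 2.652, upper = 6.334)
  ca <- list(measure = "prevalence", category = "MND",
             lower = 3.990, upper = 7.662)
  p <- pool_intervals(va, ca)
  expect_equal(c(p$lower, p$upper), c(3.990, 6.334))
  # commutative and idempotent
  q <- pool_intervals(ca, va)
  expect_equal(c(q$lower, q$upper), c(p$lower, p$upper))
  same <- pool_intervals(va, va)
  expect_equal(c(same$lower, same$upper), c(va$lower, va$upper))
  # pooled width never exceeds either input width
  expect_lte(p$upper - p$lower, va$upper - va$lower)
  expect_lte(p$upper - p$lower, ca$upper - ca$lower)
  # disjoint intervals: explicit empty result with a warning
  expect_warning(
    e <- pool_intervals(list(lower = 0, upper = 1), list(lower = 2, upper = 3)),
    "not intersect")
  expect_true(e$empty)
  expect_true(is.na(e$lower) && is.na(e$upper))
  expect_error(pool_intervals(va, list(measure = "incidence", category = "MND",
                                       lower = 1, upper = 2)),
               "measure mismatch")
})

test_that("zero_fraction and category_share reproduce descriptive values", {
  # tract-level zero structure of a two-region referral cohort
  expect_equal(zero_fraction(c(rep(0L, 3229), rep(1L, 230), rep(2L, 13), 3L)),
               93.0)
  expect_equal(zero_fraction(rep(0, 10)), 100.0)
  tr <- generate_landscape(50, seed = 2)
  sim <- simulate_disease(tr, truth_params(base_rate = 1e-9, matern = NULL),
                          2013:2018, seed = 1)
  expect_equal(zero_fraction(sim$tracts, "MND"), 100.0)
  expect_error(zero_fraction(numeric(0)), "empty")
  expect_error(zero_fraction(sim$tracts, "XXX"))

  expect_equal(unname(category_share(c(524, 14, 4))), c(96.7, 2.6, 0.7))
  expect_equal(unname(category_share(c(219, 27, 10))), c(85.5, 10.5, 3.9))
  expect_equal(unname(category_share(c(7, 7, 7))), rep(33.3, 3))
  expect_error(category_share(c(0, 0, 0)), "zero")
})

test_that("crude_rate arithmetic and its exact interval", {
  expect_equal(crude_rate(0, 1000), 0)
  expect_equal(crude_rate(259, 4180520), 6.195, tolerance = 1e-3)
  expect_equal(crude_rate(100, 50000), crude_rate(200, 100000))
  expect_equal(crude_rate(50, 10, person_years = 1e6), 5)
  expect_error(crude_rate(1, 0), "> 0")
  ci <- crude_rate_interval(100, 1e6)
  expect_lt(ci$lower, ci$point); expect_gt(ci$upper, ci$point)
  # exact Poisson interval calibration vs stats::poisson.test
  pt <- poisson.test(100)$conf.int
  expect_equal(c(ci$lower, ci$upper) * 10, c(pt[1], pt[2]), tolerance = 1e-6)
})
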