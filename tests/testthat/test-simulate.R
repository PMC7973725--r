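test_that("simulate_disease matches the Poisson oracle at a flat rate", {
  tr <- generate_landscape(200, seed = 10)
  # flat world: no covariates, no fields, no year effect
  tru <- truth_params(base_rate = 2.0, beta = c(dep_q2 = 0),
                      matern = NULL, rw1_sd = 0)
  tru$beta[] <- 0
  sim <- simulate_disease(tr, tru, 2010:2019, seed = 3)
  py <- sum(pmax(1, tr$pop_over16)) * 10
  expected <- 2.0e-5 * py
  expect_gt(expected, 90)  # enough person-years for the oracle band
  expect_lt(abs(sum(sim$tracts$cases_MND) - expected), 4 * sqrt(expected))
})

test_that("simulate_disease handles limits and conserves categories", {
  tr <- generate_landscape(50, seed = 2)
  # vanishing rate: no cases
  sim0 <- simulate_disease(tr, truth_params(base_rate = 1e-9, matern = NULL,
                                            rw1_sd = 0), 2013:2018, seed = 1)
  expect_equal(sum(sim0$tracts$cases_MND), 0)
  expect_equal(nrow(sim0$patients), 0)

  # no latent noise: tract log-rates exactly linear in covariates
  tru <- truth_params(matern = NULL, rw1_sd = 0)
  sim <- simulate_disease(tr, tru, 2013:2018, seed = 5)
  lr <- attr(sim$tracts, "truth")$log_rate
  X <- tract_design(tr)
  b <- setNames(numeric(ncol(X)), colnames(X))
  b[names(tru$beta)] <- tru$beta
  expect_equal(lr, log(2 / 1e5) + drop(X %*% b), ignore_attr = TRUE)

  # conservation: category counts sum to the MND count per tract
  sim2 <- simulate_disease(tr, truth_params(base_rate = 100), 2013:2018,
                           seed = 6)
  expect_equal(sim2$tracts$cases_MND,
               sim2$tracts$cases_ALS + sim2$tracts$cases_PMA +
                 sim2$tracts$cases_PLS)
  # per tract-year as well: records regenerate the by-year count matrix
  byyear <- tract_case_counts(sim2$patients, sim2$tracts, years = 2013:2018,
                              observed_only = FALSE)
  expect_equal(unname(byyear),
               unname(attr(sim2$tracts, "truth")$counts_by_year))
  # determinism
  expect_identical(sim2, simulate_disease(tr, truth_params(base_rate = 100),
                                          2013:2018, seed = 6))
  expect_error(simulate_disease(tr, tru, integer(), seed = 1), "empty year")
})

test_that("patient records match the stated marginals", {
  tr <- generate_landscape(300, seed = 8)
  sim <- simulate_disease(tr, truth_params(base_rate = 200, matern = NULL),
                          2013:2018, seed = 9)
  p <- sim$patients
  expect_gt(nrow(p), 3000)
  expect_lt(abs(mean(p$sex == "male") - 0.55), 0.03)
  expect_lt(abs(mean(p$age_at_diagnosis) - 63), 1)
  shares <- table(p$category) / nrow(p)
  expect_lt(abs(shares[["ALS"]] - 0.90), 0.02)
  expect_lt(abs(shares[["PMA"]] - 0.07), 0.02)
  expect_lt(abs(shares[["PLS"]] - 0.03), 0.02)
  # age quintiles are region-specific and near-balanced
  for (reg in c("A", "B")) {
    qs <- table(p$age_q[p$region == reg])
    expect_equal(length(qs), 5L)
    expect_lt(max(qs) / min(qs), 1.6)
  }
})

test_that("apply_selection thins by the stated logit probability", {
  tr <- generate_landscape(100, seed = 4)
  sim <- simulate_disease(tr, truth_params(base_rate = 300, matern = NULL),
                          2013:2018, seed = 2)
  # intercept +20: everyone observed
  all_obs <- apply_selection(sim$patients, sim$tracts,
                             selection_params(20, 0, 0), seed = 1)
  expect_true(all(all_obs$observed))
  # intercept 0, no other effects: ~half observed (3-sigma binomial band)
  half <- apply_selection(sim$patients, sim$tracts,
                          selection_params(0, 0, 0), seed = 1)
  n <- nrow(half)
  expect_gt(n, 5000)
  expect_lt(abs(mean(half$observed) - 0.5), 3 * sqrt(0.25 / n) + 0.005)
  # misaligned frailty vector
  expect_error(apply_selection(sim$patients, sim$tracts, selection_params(),
                               latent_frailty = c(1, 2), seed = 1),
               "align")
})

test_that("endogenous selection enriches high-risk tracts among observed", {
  tr <- generate_landscape(250, seed = 21)
  tru <- truth_params(base_rate = 50,
                      selection = selection_params(intercept = 0,
                                                   dist_coeff = 0,
                                                   frailty_coeff = 2))
  sim <- simulate_disease(tr, tru, 2013:2018, seed = 22)
  pats <- apply_selection(sim$patients, sim$tracts, tru$selection, seed = 23)
  lr <- attr(sim$tracts, "truth")$log_rate
  rate_by_tract <- exp(lr)[match(pats$tract_id, sim$tracts$tract_id)]
  expect_gt(mean(rate_by_tract[pats$observed]), mean(rate_by_tract))
})

test_that("exogenous limit: inverse mean observation probability recovers the rate", {
  tr <- generate_landscape(300, seed = 31)
  sel <- selection_params(frailty_coeff = 0)   # exogenous
  tru <- truth_params(base_rate = 50, matern = NULL, rw1_sd = 0,
                      selection = sel)
  tru$beta[] <- 0
  sim <- simulate_disease(tr, tru, 2013:2018, seed = 32)
  pats <- apply_selection(sim$patients, sim$tracts, sel, seed = 33)
  p <- attr(pats, "obs_prob")
  n_i <- pmax(1, sim$tracts$pop_over16)
  # per-case mean observation probability (case-weighted by tract rate)
  pbar <- weighted.mean(p, n_i)
  py <- sum(n_i) * 6
  crude <- 1e5 * sum(pats$observed) / py
  corrected <- crude / pbar
  mc_se <- 1e5 * sqrt(sum(sim$tracts$cases_MND)) / (py * pbar)
  expect_lt(abs(corrected - 50), 4 * mc_se)
  expect_lt(crude, 50)  # the crude rate underestimates
})
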