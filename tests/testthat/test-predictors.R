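test_that("part-1 predictor reduces to hand-computed values", {
  row <- c(dep_q5 = 1, male_share = 0)
  # null model: predictor 0, probability 1/2
  expect_equal(part1_linear_predictor(row, c(intercept = 0, dep_q5 = 0)), 0)
  expect_equal(plogis(0), 0.5)
  # worked example: -8 + 0.3 on the Q5 row
  lp <- part1_linear_predictor(row, c(intercept = -8, dep_q5 = 0.3))
  expect_equal(lp, -7.7)
  expect_equal(plogis(lp), 4.527e-4, tolerance = 1e-3)
  # linearity in the intercept
  lp2 <- part1_linear_predictor(row, c(intercept = -8 + 1.5, dep_q5 = 0.3))
  expect_equal(lp2 - lp, 1.5)
  # latent effects add on
  lat <- latent_state(eta1 = c(0.2, -0.1), S = c(0.05, 0))
  expect_equal(part1_linear_predictor(row, c(intercept = -8, dep_q5 = 0.3),
                                      lat, tract = 1),
               -7.7 + 0.25)
  expect_error(part1_linear_predictor(c(dep_q2 = 1),
                                      c(intercept = 0, dep_q5 = 1)),
               "dep_q5")
})

test_that("part-2 predictor carries offset and weighting", {
  row <- c(dep_q2 = 0)
  # offset-only model
  lp <- part2_linear_predictor(row, c(intercept = 0, dep_q2 = 0),
                               pop_over16 = 1e5)
  expect_equal(exp(lp), 1e5)
  # doubling the offset population doubles theta
  lp2 <- part2_linear_predictor(row, c(intercept = 0, dep_q2 = 0),
                                pop_over16 = 2e5)
  expect_equal(exp(lp2), 2 * exp(lp))
  # ~2 per 100,000 rate
  lp3 <- part2_linear_predictor(row, c(intercept = -10.8, dep_q2 = 0),
                                pop_over16 = 1e5)
  expect_equal(exp(lp3), 1e5 * exp(-10.8))
  expect_equal(exp(lp3), 2.04, tolerance = 0.01)
  # weighting term shifts the log mean
  lp4 <- part2_linear_predictor(row, c(intercept = -10.8, dep_q2 = 0),
                                pop_over16 = 1e5, weight_term = log(0.5))
  expect_equal(exp(lp4), 0.5 * exp(lp3))
  expect_error(part2_linear_predictor(row, c(intercept = 0, dep_q2 = 0),
                                      pop_over16 = 0), "> 0")
})

test_that("joint log-likelihood matches a hand oracle and is additive", {
  # empty data
  expect_equal(joint_loglikelihood(integer(), integer(),
                                   data.frame(), c(intercept = 0),
                                   c(intercept = 0)), 0)
  # single tract, y = 0: hand computation of both parts
  n <- 1000L
  c1 <- c(intercept = -7, dep_q5 = 0.4)
  c2 <- c(intercept = -9, dep_q5 = 0.2)
  lat <- latent_state(eta1 = 0.1, eta2 = -0.2, S = 0.3, pi0 = 0.15)
  design <- data.frame(dep_q5 = 1)
  wt <- log(0.8)
  p <- plogis(-7 + 0.4 + 0.1 + 0.3)
  theta <- exp(-9 + 0.2 - 0.2 + 0.3 + log(n) + wt)
  hand <- dbinom(0, n, p, log = TRUE) +
    log(0.15 + 0.85 * exp(-theta))
  expect_equal(joint_loglikelihood(0L, n, design, c1, c2, lat, wt),
               hand, tolerance = 1e-10)
  # decoupled additivity: total = part1 + part2 computed independently
  set.seed(9)
  counts <- rpois(6, 2)
  trials <- rep(5000L, 6)
  design <- data.frame(dep_q5 = rbinom(6, 1, 0.4))
  l_both <- joint_loglikelihood(counts, trials, design, c1, c2)
  l1 <- joint_loglikelihood(counts, trials, design, c1, c2,
                            parts = "binomial")
  l2 <- joint_loglikelihood(counts, trials, design, c1, c2, parts = "zip")
  expect_equal(l_both, l1 + l2, tolerance = 1e-12)
  expect_error(joint_loglikelihood(c(1, 2), 5L, design, c1, c2), "mismatch")
})

test_that("predictors reduce to plain GLM predictors without random effects", {
  set.seed(4)
  X <- data.frame(dep_q2 = rbinom(10, 1, 0.5), male_share = runif(10, -1, 1))
  cf <- c(intercept = -2, dep_q2 = 0.5, male_share = -0.3)
  for (i in 1:10) {
    lp_glm <- -2 + 0.5 * X$dep_q2[i] - 0.3 * X$male_share[i]
    expect_equal(part1_linear_predictor(X[i, ], cf), lp_glm)
    expect_equal(part2_linear_predictor(X[i, ], cf, pop_over16 = 100),
                 lp_glm + log(100))
  }
})
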