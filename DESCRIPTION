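Package: mndrates
Title: Two-Part Bayesian Spatial Estimation of Motor Neuron Disease Rates
Version: 0.1.0
Authors@R: person("mndrates", "developers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates the prevalence and incidence of rare neurological
    diseases (motor neuron disease and its diagnostic categories) from
    non-random referral-unit cohorts aggregated at the census-tract level.
    Implements a jointly estimated two-part (hurdle) model: a binomial
    observation component and a zero-inflated Poisson count component,
    coupled through a shared Matern Gaussian spatial field, tract-level
    unstructured heterogeneity, an optional first-order random-walk year
    effect, and penalized-complexity priors.  Posterior computation uses a
    nested Laplace approximation with empirical-Bayes hyperparameters.
    Also ships a seeded synthetic census-tract landscape generator with
    endogenous (selection-on-unobservables) observation processes, a
    sequential principal-component deprivation index, region-level rate
    estimation with credibility-interval pooling, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
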