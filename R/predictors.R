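# Linear predictors and joint likelihood of the two-part model, written as
# directly evaluable functions of a design row, coefficient vectors and a
# latent state.  These are the mathematical surface of the model; the
# fitting engine assembles the same quantities in vectorised form.

#' Latent state of the two-part model
#'
#' @param eta1,eta2 per-tract iid heterogeneity, one vector per part.
#' @param S shared spatial field per tract.
#' @param gamma RW1 year effects (possibly length 0 for prevalence).
#' @param pi0 zero-inflation probability in \[0, 1\].
#' @return Object of class `latent_state`.
#' @export
latent_state <- function(eta1 = 0, eta2 = 0, S = 0, gamma = numeric(),
                         pi0 = 0) {
  n <- max(length(eta1), length(eta2), length(S))
  eta1 <- rep_len(eta1, n); eta2 <- rep_len(eta2, n); S <- rep_len(S, n)
  stopifnot(is.numeric(pi0), length(pi0) == 1L, pi0 >= 0, pi0 <= 1,
            all(is.finite(c(eta1, eta2, S, gamma))))
  structure(list(eta1 = eta1, eta2 = eta2, S = S, gamma = gamma, pi0 = pi0),
            class = "latent_state")
}

.coef_times_row <- function(design_row, coefficients, part) {
  cov_names <- setdiff(names(coefficients), "intercept")
  missing_cov <- setdiff(cov_names, names(design_row))
  if (length(missing_cov))
    stop(part, " linear predictor: design row is missing covariate(s): ",
         paste(missing_cov, collapse = ", "))
  b0 <- if ("intercept" %in% names(coefficients))
    unname(coefficients[["intercept"]]) else 0
  b0 + sum(unlist(coefficients[cov_names]) *
             unlist(design_row[cov_names]))
}

#' Part-1 (observation) linear predictor
#'
#' The logit of the probability of being observed at tract `tract`:
#' intercept + eta1 + S + covariate terms.  The probability itself is
#' `plogis()` of the returned value.
#'
#' @param design_row named numeric vector (or one-row data frame) of
#'   covariate values.
#' @param coefficients named vector/list of coefficients; the optional
#'   `intercept` element is the intercept, all other names must match
#'   `design_row` entries.
#' @param latent a [latent_state()] (or NULL for no random effects).
#' @param tract index into the latent vectors.
#' @return The linear predictor (logit scale), a scalar.
#' @export
part1_linear_predictor <- function(design_row, coefficients, latent = NULL,
                                   tract = 1L) {
  lp <- .coef_times_row(design_row, coefficients, "part-1")
  if (!is.null(latent)) {
    stopifnot(inherits(latent, "latent_state"))
    lp <- lp + latent$eta1[tract] + latent$S[tract]
  }
  lp
}

#' Part-2 (count) linear predictor
#'
#' The log of the expected count at tract `tract`: the same structural form
#' as part 1 on the log scale, plus the log population-at-risk offset, plus
#' the part-1 weighting term prescribed by the coupling rule, plus (for
#' incidence models) the RW1 year effect.
#'
#' @inheritParams part1_linear_predictor
#' @param pop_over16 population at risk used as offset; must be > 0.
#' @param weight_term the part-1 weighting contribution (log observation
#'   probability under the `log_prob_offset` rule); 0 when decoupled.
#' @param year index into `latent$gamma`, or NULL for no temporal effect.
#' @return The linear predictor (log scale), a scalar: `log(theta)`.
#' @export
part2_linear_predictor <- function(design_row, coefficients, latent = NULL,
                                   pop_over16 = 1, weight_term = 0,
                                   tract = 1L, year = NULL) {
  if (!is.numeric(pop_over16) || pop_over16 <= 0)
    stop("part-2 linear predictor: 'pop_over16' offset must be > 0")
  lp <- .coef_times_row(design_row, coefficients, "part-2") +
    log(pop_over16) + weight_term
  if (!is.null(latent)) {
    stopifnot(inherits(latent, "latent_state"))
    lp <- lp + latent$eta2[tract] + latent$S[tract]
    if (!is.null(year)) lp <- lp + latent$gamma[year]
  }
  lp
}

#' Joint log-likelihood of the two-part model
#'
#' Sum over tracts of the part-1 binomial log-likelihood (trials = the
#' population at risk) and the part-2 zero-inflated Poisson log-likelihood,
#' coupled through the shared spatial field carried by `latent` and the
#' part-1 weighting terms.
#'
#' @param counts observed case counts, one per tract.
#' @param trials population at risk per tract (binomial trials and part-2
#'   offset).
#' @param design matrix or data frame of covariates, one row per tract.
#' @param coef1,coef2 named coefficient vectors for the two parts (see
#'   [part1_linear_predictor()]).
#' @param latent a [latent_state()] or NULL.
#' @param weight_term per-tract part-1 weighting contribution to part 2
#'   (recycled; 0 when decoupled).
#' @param parts character subset of `c("binomial", "zip")`.
#' @return Total log-likelihood (scalar); 0 for empty data.
#' @export
joint_loglikelihood <- function(counts, trials, design, coef1, coef2,
                                latent = NULL, weight_term = 0,
                                parts = c("binomial", "zip")) {
  n <- length(counts)
  if (n == 0L) return(0)
  if (length(trials) != n)
    stop("joint_loglikelihood: 'counts' and 'trials' dimension mismatch")
  design <- as.data.frame(design)
  if (nrow(design) != n)
    stop("joint_loglikelihood: 'design' dimension mismatch")
  weight_term <- rep_len(weight_term, n)
  pi0 <- if (!is.null(latent)) latent$pi0 else 0
  ll <- 0
  for (i in seq_len(n)) {
    row <- design[i, , drop = FALSE]
    if ("binomial" %in% parts) {
      p <- stats::plogis(part1_linear_predictor(row, coef1, latent, tract = i))
      ll <- ll + stats::dbinom(counts[i], trials[i], p, log = TRUE)
    }
    if ("zip" %in% parts) {
      theta <- exp(part2_linear_predictor(row, coef2, latent,
                                          pop_over16 = trials[i],
                                          weight_term = weight_term[i],
                                          tract = i))
      ll <- ll + zip_logpmf(counts[i], theta, pi0)
    }
  }
  ll
}
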