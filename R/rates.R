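# Region- and tract-level rate estimation, credibility-interval pooling and
# the descriptive computations used for cohort tables.

.rate_estimate <- function(scope, measure, category, point, lower, upper,
                           extra = NULL) {
  out <- data.frame(scope = scope, measure = measure, category = category,
                    point = point, lower = lower, upper = upper,
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  class(out) <- c("rate_estimate", "data.frame")
  out
}

# posterior draws of the region-level rate per 100,000 at-risk
# person-years implied by a coupled fit
.region_rate_draws <- function(fit) {
  if (is.null(fit$draws$log_rate))
    stop("rate estimation needs a coupled fit with disease log-rate draws")
  n_i <- fit$data$pop_over16
  E <- exp(fit$draws$log_rate)              # draws x tracts, rate per py
  if (!is.null(fit$draws$gamma)) {
    yr_mult <- rowMeans(exp(fit$draws$gamma))  # average year effect
    E <- E * yr_mult
  }
  1e5 * as.vector(E %*% n_i) / sum(n_i)
}

#' Region-level prevalence estimate
#'
#' Posterior expected cases over the study window divided by the total
#' at-risk population, times 100,000: a period prevalence per 100,000
#' at-risk inhabitants, summarised by the posterior median and equal-tailed
#' 95% credibility interval.  The estimate comes from the model's disease
#' surface (the corrected rate), not from the crude observed-count ratio.
#'
#' @param fit a coupled `two_part_fit` with `target = "prevalence"`.
#' @param category diagnostic category label for the output row; defaults
#'   to the fitted response.
#' @return A one-row `rate_estimate` data frame.
#' @export
region_prevalence <- function(fit, category = fit$spec$response) {
  stopifnot(inherits(fit, "two_part_fit"))
  if (fit$spec$target != "prevalence")
    stop("region_prevalence: fit has target '", fit$spec$target, "'")
  if (sum(fit$data$pop_over16) <= 0) stop("region_prevalence: zero population")
  dr <- .region_rate_draws(fit) * fit$data$window_years
  s <- posterior_summary(dr)
  .rate_estimate(scope = paste(unique(fit$data$region), collapse = "+"),
                 measure = "prevalence", category = category,
                 point = s$point, lower = s$lower, upper = s$upper)
}

#' Region-level incidence estimate
#'
#' Posterior expected new cases per year divided by at-risk person-years,
#' times 100,000, with the RW1 year effects averaged over the period.
#'
#' @param fit a coupled `two_part_fit` with `target = "incidence"`.
#' @param category diagnostic category label; defaults to the fitted
#'   response.
#' @param period years to average over; defaults to the fitted window.
#' @return A one-row `rate_estimate` data frame.
#' @export
region_incidence <- function(fit, category = fit$spec$response,
                             period = fit$data$years) {
  stopifnot(inherits(fit, "two_part_fit"))
  if (fit$spec$target != "incidence")
    stop("region_incidence: fit has target '", fit$spec$target, "'")
  if (length(period) < 1L) stop("region_incidence: empty period")
  n_i <- fit$data$pop_over16
  E <- exp(fit$draws$log_rate)
  if (!is.null(fit$draws$gamma)) {
    keep <- which(fit$data$years %in% period)
    if (!length(keep)) stop("region_incidence: period outside fitted years")
    E <- E * rowMeans(exp(fit$draws$gamma[, keep, drop = FALSE]))
  }
  dr <- 1e5 * as.vector(E %*% n_i) / sum(n_i)
  s <- posterior_summary(dr)
  .rate_estimate(scope = paste(unique(fit$data$region), collapse = "+"),
                 measure = "incidence", category = category,
                 point = s$point, lower = s$lower, upper = s$upper)
}

#' Tract-level rate estimates
#'
#' Per-tract posterior rate summaries (per 100,000 at-risk person-years).
#' Tracts whose at-risk population falls below `pop_floor` are flagged
#' `unstable`: their point estimates rest on almost no information and must
#' be interpreted with caution.
#'
#' @param fit a coupled `two_part_fit`.
#' @param pop_floor at-risk population below which a tract is flagged.
#' @return A `rate_estimate` data frame with one row per tract and an
#'   `unstable` flag column.
#' @export
tract_rates <- function(fit, pop_floor = 50) {
  stopifnot(inherits(fit, "two_part_fit"))
  if (is.null(fit$draws$log_rate))
    stop("tract_rates: fit has no disease log-rate draws")
  E <- 1e5 * exp(fit$draws$log_rate)
  if (!is.null(fit$draws$gamma)) E <- E * rowMeans(exp(fit$draws$gamma))
  point <- apply(E, 2, stats::median)
  lo <- apply(E, 2, stats::quantile, 0.025)
  hi <- apply(E, 2, stats::quantile, 0.975)
  .rate_estimate(scope = fit$data$tract_id,
                 measure = paste0(fit$spec$target, "_rate_py"),
                 category = fit$spec$response,
                 point = point, lower = lo, upper = hi,
                 extra = list(pop_over16 = fit$data$pop_over16,
                              unstable = fit$data$pop_over16 < pop_floor))
}

#' Pool two credibility intervals by intersection
#'
#' Combines the per-region 95% credibility intervals into the interval both
#' regions support: `[max(lower), min(upper)]`.  An empty intersection is
#' returned explicitly (NA bounds, `empty = TRUE`) with a warning, never
#' silently clamped.
#'
#' @param a,b one-row `rate_estimate` data frames (or lists with `lower`,
#'   `upper` and optionally `measure`/`category`) for the same measure and
#'   category.
#' @return A one-row data frame with `lower`, `upper` and `empty`.
#' @examples
#' va <- list(measure = "prevalence", category = "MND",
#'            lower = 2.652, upper = 6.334)
#' ca <- list(measure = "prevalence", category = "MND",
#'            lower = 3.990, upper = 7.662)
#' pool_intervals(va, ca)  # [3.990, 6.334]
#' @export
pool_intervals <- function(a, b) {
  gets <- function(x, f) if (!is.null(x[[f]])) x[[f]][1] else NA
  for (f in c("measure", "category")) {
    fa <- gets(a, f); fb <- gets(b, f)
    if (!is.na(fa) && !is.na(fb) && fa != fb)
      stop("pool_intervals: ", f, " mismatch ('", fa, "' vs '", fb, "')")
  }
  lo <- max(a$lower, b$lower)
  hi <- min(a$upper, b$upper)
  empty <- lo > hi
  if (empty) {
    warning("pool_intervals: credibility intervals do not intersect")
    lo <- NA_real_; hi <- NA_real_
  }
  data.frame(measure = gets(a, "measure"), category = gets(a, "category"),
             lower = lo, upper = hi, empty = empty,
             stringsAsFactors = FALSE)
}

#' Percentage of tracts with zero cases
#'
#' @param tracts a `tract_table` with `cases_*` columns, or a plain numeric
#'   vector of per-tract counts.
#' @param category "MND", "ALS", "PMA" or "PLS" (ignored for a vector).
#' @return Percentage of tracts with zero cases of the category, rounded to
#'   one decimal.
#' @export
zero_fraction <- function(tracts, category = "MND") {
  counts <- if (is.numeric(tracts)) tracts
  else {
    col <- paste0("cases_", match.arg(category, c("MND", "ALS", "PMA", "PLS")))
    if (!col %in% names(tracts))
      stop("zero_fraction: missing column '", col, "'")
    tracts[[col]]
  }
  if (length(counts) == 0L) stop("zero_fraction: empty tract table")
  round(100 * mean(counts == 0), 1)
}

#' Diagnostic-category shares among definite diagnoses
#'
#' @param counts named or positionally ordered counts for ALS, PMA, PLS.
#' @return Percentages summing to ~100, rounded to one decimal, named.
#' @examples
#' category_share(c(ALS = 524, PMA = 14, PLS = 4))  # 96.7 2.6 0.7
#' @export
category_share <- function(counts) {
  stopifnot(is.numeric(counts), length(counts) == 3L, all(counts >= 0))
  if (sum(counts) == 0) stop("category_share: all categories are zero")
  if (is.null(names(counts))) names(counts) <- c("ALS", "PMA", "PLS")
  round(100 * counts / sum(counts), 1)
}

#' Crude rate per 100,000
#'
#' The naive observed-count ratio, the comparator that the corrected
#' model-based estimate is measured against.  Uses `person_years` as the
#' denominator when supplied, else `population`.
#'
#' @param cases observed case count, >= 0.
#' @param population persons at risk, > 0.
#' @param person_years optional person-years denominator.
#' @return Rate per 100,000 (scalar).
#' @export
crude_rate <- function(cases, population, person_years = NULL) {
  den <- if (!is.null(person_years)) person_years else population
  if (is.null(den) || !is.finite(den) || den <= 0)
    stop("crude_rate: denominator must be > 0")
  stopifnot(cases >= 0)
  1e5 * cases / den
}

#' Exact Poisson interval for a crude rate
#'
#' Garwood exact 95% confidence interval for the crude rate, used to show
#' that under selection the naive estimate excludes the truth.
#'
#' @inheritParams crude_rate
#' @return List with `point`, `lower`, `upper` (per 100,000).
#' @export
crude_rate_interval <- function(cases, population, person_years = NULL) {
  den <- if (!is.null(person_years)) person_years else population
  if (den <= 0) stop("crude_rate_interval: denominator must be > 0")
  lo <- if (cases == 0) 0 else stats::qgamma(0.025, cases) / den
  hi <- stats::qgamma(0.975, cases + 1) / den
  list(point = 1e5 * cases / den, lower = 1e5 * lo, upper = 1e5 * hi)
}
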