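# Model specification containers for the two-part (hurdle) model.

#' Penalised-complexity prior settings
#'
#' Tail statements calibrating the PC priors: `P(sigma > sd_u) = sd_alpha`
#' for every random-effect standard deviation, and
#' `P(rho < range_u) = range_alpha` for the spatial practical range.
#'
#' @param sd_u,sd_alpha scale and tail probability for sd priors.  Default
#'   `P(sigma > 1) = 0.01`, a weakly-informative calibration for effects on
#'   the log/logit scale.
#' @param range_u range threshold; `NULL` (default) means one tenth of the
#'   domain diameter, resolved at fit time.
#' @param range_alpha probability that the range falls below `range_u`.
#' @return Object of class `pc_prior_settings`.
#' @export
pc_prior_settings <- function(sd_u = 1, sd_alpha = 0.01,
                              range_u = NULL, range_alpha = 0.05) {
  stopifnot(sd_u > 0, sd_alpha > 0, sd_alpha < 1,
            is.null(range_u) || range_u > 0,
            range_alpha > 0, range_alpha < 1)
  structure(list(sd_u = sd_u, sd_alpha = sd_alpha, range_u = range_u,
                 range_alpha = range_alpha), class = "pc_prior_settings")
}

#' Specification of the jointly estimated two-part model
#'
#' Describes both parts of the hurdle model: the binomial observation part
#' and the zero-inflated Poisson count part, their shared Matern spatial
#' field, per-part unstructured heterogeneity, the RW1 year effect (enabled
#' exactly when `target = "incidence"`), the selection (observation) model
#' and the rule coupling the part-1 observation probabilities into part 2.
#'
#' Reference categories are deprivation quintile 1 and the male sex;
#' individual sex and age covariates enter the tract-level equations as
#' at-risk composition shares (see [tract_design()]).
#'
#' @param response which case count is modelled: "MND", "ALS", "PMA", "PLS".
#' @param target "prevalence" (per 100,000 inhabitants at risk over the
#'   study window) or "incidence" (per 100,000 person-years, with RW1 year
#'   effects).
#' @param fixed_effects names of [tract_design()] columns to include.
#' @param selection include the observation (selection) model: a distance-
#'   to-referral-centre effect plus, when `endogenous = TRUE`, a loading of
#'   the shared spatial field on the observation logit.
#' @param endogenous allow selection on unobservables (shared-field loading
#'   `c_s` estimated); ignored when `selection = FALSE`.
#' @param coverage_at_centre assumed capture probability of a case arising
#'   at the referral centre itself (distance 0, zero frailty).  This anchors
#'   the absolute scale of the observation probabilities -- without an
#'   anchor a thinned count model cannot separate rate from coverage.
#' @param weighting_rule how part-1 probabilities weight part 2:
#'   `"log_prob_offset"` (default) adds `log P(observed)` to the part-2
#'   linear predictor so the count mean models observed counts as thinned
#'   true counts; `"likelihood_weight"` instead weights the part-2
#'   likelihood terms by the inverse observation probability.
#' @param spatial include the shared Matern spatial field.
#' @param heterogeneity include iid tract-level heterogeneity in the count
#'   part.
#' @param nu Matern smoothness, fixed (default 1).
#' @param estimate_pi0 estimate the zero-inflation mass (uniform(0,1)
#'   prior); if FALSE, `pi0` is fixed at 0.
#' @param coupled couple the two parts (shared field, shared disease
#'   surface, weighting).  `FALSE` gives each part its own coefficients and
#'   no shared terms: the joint fit then factorises into two independent
#'   GLM(M)s, the decoupled limit used for validation.
#' @param parts which likelihood parts to include ("binomial", "zip").
#' @param priors a [pc_prior_settings()] object.
#' @return Object of class `two_part_spec`.
#' @export
two_part_spec <- function(response = c("MND", "ALS", "PMA", "PLS"),
                          target = c("prevalence", "incidence"),
                          fixed_effects = tract_design_template(),
                          selection = TRUE,
                          endogenous = TRUE,
                          coverage_at_centre = 0.95,
                          weighting_rule = c("log_prob_offset",
                                             "likelihood_weight"),
                          spatial = TRUE,
                          heterogeneity = TRUE,
                          nu = 1,
                          estimate_pi0 = TRUE,
                          coupled = TRUE,
                          parts = c("binomial", "zip"),
                          priors = pc_prior_settings()) {
  response <- match.arg(response)
  target <- match.arg(target)
  weighting_rule <- match.arg(weighting_rule)
  parts <- match.arg(parts, several.ok = TRUE)
  stopifnot(inherits(priors, "pc_prior_settings"), nu > 0,
            coverage_at_centre > 0, coverage_at_centre < 1)
  structure(list(response = response, target = target,
                 fixed_effects = fixed_effects,
                 selection = isTRUE(selection),
                 endogenous = isTRUE(endogenous),
                 coverage_at_centre = coverage_at_centre,
                 weighting_rule = weighting_rule,
                 spatial = isTRUE(spatial),
                 heterogeneity = isTRUE(heterogeneity),
                 nu = nu, estimate_pi0 = isTRUE(estimate_pi0),
                 coupled = isTRUE(coupled), parts = parts,
                 temporal_rw1 = target == "incidence",
                 priors = priors),
            class = "two_part_spec")
}

# template design column names without needing a tract table
tract_design_template <- function() {
  c("dep_q2", "dep_q3", "dep_q4", "dep_q5", "male_share", "age65_share",
    "log_men_16to64", "log_men_65plus", "log_women_16to64",
    "log_women_65plus")
}

#' @export
print.two_part_spec <- function(x, ...) {
  cat(sprintf(
    "Two-part model spec: response %s, target %s%s\n  parts: %s%s; selection: %s%s\n  weighting: %s; pi0 %s; nu = %g\n",
    x$response, x$target, if (x$temporal_rw1) " (RW1 year effect)" else "",
    paste(x$parts, collapse = " + "),
    if (x$coupled) " (coupled)" else " (decoupled)",
    if (x$selection) sprintf("on (anchor %.2f", x$coverage_at_centre) else "off",
    if (x$selection) paste0(if (x$endogenous) ", endogenous)" else ")") else "",
    x$weighting_rule, if (x$estimate_pi0) "estimated" else "fixed at 0", x$nu))
  invisible(x)
}

#' Serialise / restore a model spec
#'
#' Round-trip a [two_part_spec()] through JSON, e.g. for run logging.
#'
#' @param spec a `two_part_spec`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return `spec_to_json`: JSON string (invisibly, when written to a file);
#'   `spec_from_json`: the restored `two_part_spec`.
#' @export
spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "two_part_spec"))
  x <- unclass(spec)
  x$priors <- unclass(x$priors)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname spec_to_json
#' @param json JSON string or path to a JSON file.
#' @export
spec_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  x <- jsonlite::fromJSON(paste(json, collapse = "\n"))
  pr <- do.call(pc_prior_settings, x$priors)
  two_part_spec(response = x$response, target = x$target,
                fixed_effects = x$fixed_effects, selection = x$selection,
                endogenous = x$endogenous,
                coverage_at_centre = x$coverage_at_centre,
                weighting_rule = x$weighting_rule, spatial = x$spatial,
                heterogeneity = x$heterogeneity, nu = x$nu,
                estimate_pi0 = x$estimate_pi0, coupled = x$coupled,
                parts = x$parts, priors = pr)
}
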