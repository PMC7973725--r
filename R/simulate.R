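# True disease process and selection-biased observation on a synthetic
# landscape.  The generator inverts the inference model: Poisson tract-year
# counts with a log-rate built from covariates, a Matern spatial field and
# an RW1 year effect, thinned by a per-tract observation probability that
# may depend on the same latent field (endogenous selection).

# reference constants used to centre design columns; fixed (rather than
# sample means) so the same design applies across simulated datasets
.design_centres <- list(male_share = 0.5, age65_share = 0.17,
                        log_pop_ref = 1400)

#' Tract-level design matrix for both model parts
#'
#' Builds the fixed-effect design used by the simulator and the model:
#' deprivation-quintile dummies (quintile 1 is the reference), the male
#' share and the 65+ share of the at-risk population (centred at fixed
#' reference values, so individual sex/age covariates of the written model
#' enter as tract-level composition shares), and the four log population
#' strata (centred at their expected value for a median-sized tract).
#'
#' @param tracts a `tract_table`.
#' @return Numeric matrix with one row per tract and named columns
#'   `dep_q2`..`dep_q5`, `male_share`, `age65_share`, `log_men_16to64`,
#'   `log_men_65plus`, `log_women_16to64`, `log_women_65plus`.
#' @export
tract_design <- function(tracts) {
  need <- c("deprivation_q", "pop_over16", "men_16to64", "men_65plus",
            "women_16to64", "women_65plus")
  miss <- setdiff(need, names(tracts))
  if (length(miss))
    stop("tract_design: missing tract columns: ", paste(miss, collapse = ", "))
  over16 <- pmax(1L, tracts$pop_over16)
  ref <- .design_centres
  strata_ref <- function(nm) log1p(.strata_props[[nm]] * ref$log_pop_ref)
  X <- cbind(
    dep_q2 = as.numeric(tracts$deprivation_q == 2L),
    dep_q3 = as.numeric(tracts$deprivation_q == 3L),
    dep_q4 = as.numeric(tracts$deprivation_q == 4L),
    dep_q5 = as.numeric(tracts$deprivation_q == 5L),
    male_share = (tracts$men_16to64 + tracts$men_65plus) / over16 -
      ref$male_share,
    age65_share = (tracts$men_65plus + tracts$women_65plus) / over16 -
      ref$age65_share,
    log_men_16to64 = log1p(tracts$men_16to64) - strata_ref("men_16to64"),
    log_men_65plus = log1p(tracts$men_65plus) - strata_ref("men_65plus"),
    log_women_16to64 = log1p(tracts$women_16to64) - strata_ref("women_16to64"),
    log_women_65plus = log1p(tracts$women_65plus) - strata_ref("women_65plus"))
  rownames(X) <- tracts$tract_id
  X
}

#' Default fixed-effect truth for the simulator
#'
#' A modest deprivation gradient (relative risk ~1.3 in the most deprived
#' quintile), a positive male-composition effect consistent with the 1.3-1.5
#' male-to-female incidence ratio, a positive 65+ composition effect, and
#' null effects of the log population strata beyond the offset.
#'
#' @return Named numeric vector aligned with [tract_design()] columns.
#' @export
default_truth_beta <- function() {
  c(dep_q2 = 0.05, dep_q3 = 0.10, dep_q4 = 0.18, dep_q5 = 0.26,
    male_share = 0.5, age65_share = 1.0,
    log_men_16to64 = 0, log_men_65plus = 0,
    log_women_16to64 = 0, log_women_65plus = 0)
}

#' Selection (observation) process parameters
#'
#' The probability that a true case is captured by the region's referral
#' unit is `plogis(intercept + dist_coeff * distance_km + frailty_coeff *
#' frailty)`.  `frailty_coeff = 0` makes selection exogenous (driven only by
#' observables); a nonzero value couples observation to the tract's latent
#' risk, the endogenous (selection-on-unobservables) regime the two-part
#' model is designed to correct.
#'
#' The defaults state a world where coverage at the referral centre's
#' doorstep is ~95% and decays with distance to a region-wide mean capture
#' of about 60% -- the coverage level implied by comparing referral-cohort
#' counts with corrected incidence in two-region MND surveillance data.
#'
#' @param intercept logit-scale coverage at distance zero and zero frailty.
#' @param dist_coeff logit change per km of distance to the referral centre.
#' @param frailty_coeff logit effect of the tract's latent spatial/
#'   heterogeneity effect.
#' @return Object of class `selection_params`.
#' @export
selection_params <- function(intercept = stats::qlogis(0.95),
                             dist_coeff = -0.115, frailty_coeff = 0) {
  stopifnot(is.numeric(intercept), is.numeric(dist_coeff),
            is.numeric(frailty_coeff))
  structure(list(intercept = intercept, dist_coeff = dist_coeff,
                 frailty_coeff = frailty_coeff), class = "selection_params")
}

#' Ground-truth parameters for the disease simulator
#'
#' @param base_rate true disease rate, new cases per 100,000 person-years of
#'   at-risk (over-16) population; > 0.  Default 2.0, in the 2-6 per 100,000
#'   band typical of motor neuron disease incidence.
#' @param beta named fixed-effect vector on [tract_design()] columns;
#'   missing names are taken as 0.
#' @param matern a [matern_params()] object for the latent spatial field, or
#'   `NULL` for no spatial effect.  Default: sd 0.3, practical range 15 km.
#' @param rw1_sd standard deviation of the RW1 year-effect increments; 0
#'   disables the temporal effect.
#' @param eta_sd standard deviation of iid tract-level log-rate
#'   heterogeneity (0 by default: all latent structure is spatial).
#' @param selection a [selection_params()] object.
#' @return Object of class `truth_params`.
#' @export
truth_params <- function(base_rate = 2.0, beta = default_truth_beta(),
                         matern = matern_params_from_range(0.09, 15),
                         rw1_sd = 0.05, eta_sd = 0,
                         selection = selection_params()) {
  if (!is.numeric(base_rate) || base_rate <= 0)
    stop("truth_params: 'base_rate' must be > 0")
  if (rw1_sd < 0 || eta_sd < 0)
    stop("truth_params: variance parameters must be >= 0")
  if (!is.null(matern)) stopifnot(inherits(matern, "matern_params"))
  stopifnot(inherits(selection, "selection_params"))
  structure(list(base_rate = base_rate, beta = beta, matern = matern,
                 rw1_sd = rw1_sd, eta_sd = eta_sd, selection = selection),
            class = "truth_params")
}

.beta_on_design <- function(beta, X) {
  b <- stats::setNames(numeric(ncol(X)), colnames(X))
  known <- intersect(names(beta), colnames(X))
  b[known] <- beta[known]
  drop(X %*% b)
}

#' Simulate the true disease process on a landscape
#'
#' Draws true new-case counts per tract-year from a Poisson law with
#' \deqn{\log E[N_{it}] = \log(\mathrm{base\_rate}/10^5) + x_i^T\beta +
#'   S(x_i) + \eta_i + \gamma_t + \log(\mathrm{pop\_over16}_i)}
#' and expands the counts into patient records with sex (male fraction
#' 0.55), age at diagnosis (normal, mean 63, sd 12, truncated to 21-95) and
#' diagnostic category (ALS 0.90, PMA 0.07, PLS 0.03).
#'
#' @param tracts a `tract_table` from [generate_landscape()].
#' @param truth a [truth_params()] object.
#' @param years integer vector of calendar years (the study period).
#' @param seed integer seed.
#' @return List with `tracts` (input plus per-category total case counts and
#'   a `truth` attribute holding the latent field, year effects and log
#'   rates) and `patients` (a `data.frame` of patient records, all with
#'   `observed = TRUE` until [apply_selection()] is run).
#' @export
simulate_disease <- function(tracts, truth, years, seed) {
  stopifnot(inherits(truth, "truth_params"))
  if (length(years) < 1L) stop("simulate_disease: empty year range")
  years <- as.integer(years)
  set.seed(seed)
  n <- nrow(tracts)
  Tn <- length(years)

  S <- if (is.null(truth$matern)) numeric(n) else
    sample_matern_field(cbind(tracts$x, tracts$y), truth$matern)
  eta <- if (truth$eta_sd > 0) stats::rnorm(n, 0, truth$eta_sd) else numeric(n)
  gamma <- if (truth$rw1_sd > 0 && Tn > 1L) {
    g <- cumsum(c(0, stats::rnorm(Tn - 1L, 0, truth$rw1_sd)))
    g - mean(g)
  } else numeric(Tn)

  X <- tract_design(tracts)
  log_rate <- log(truth$base_rate / 1e5) + .beta_on_design(truth$beta, X) +
    S + eta
  mu <- outer(pmax(1L, tracts$pop_over16) * exp(log_rate), exp(gamma))
  counts <- matrix(stats::rpois(n * Tn, mu), n, Tn,
                   dimnames = list(tracts$tract_id, years))

  total <- sum(counts)
  cats <- c("ALS", "PMA", "PLS")
  patients <- if (total > 0) {
    tract_idx <- rep(rep(seq_len(n), Tn), as.vector(counts))
    year_vec <- rep(rep(years, each = n), as.vector(counts))
    age <- pmin(95, pmax(21, round(stats::rnorm(total, 63, 12))))
    data.frame(
      patient_id = sprintf("P%06d", seq_len(total)),
      tract_id = tracts$tract_id[tract_idx],
      region = tracts$region[tract_idx],
      sex = ifelse(stats::runif(total) < 0.55, "male", "female"),
      age_at_diagnosis = age,
      age_q = NA_integer_,
      year = year_vec,
      category = sample(cats, total, replace = TRUE,
                        prob = c(0.90, 0.07, 0.03)),
      observed = TRUE,
      stringsAsFactors = FALSE)
  } else {
    data.frame(patient_id = character(), tract_id = character(),
               region = character(), sex = character(),
               age_at_diagnosis = numeric(), age_q = integer(),
               year = integer(), category = character(),
               observed = logical(), stringsAsFactors = FALSE)
  }
  # region-specific age quintiles, as in referral-cohort descriptive tables
  for (reg in unique(patients$region)) {
    sel <- patients$region == reg
    patients$age_q[sel] <- if (sum(sel) >= 5L)
      quintile_categorise(patients$age_at_diagnosis[sel]) else 1L
  }

  out <- tracts
  out$cases_MND <- as.integer(rowSums(counts))
  for (ct in cats)
    out[[paste0("cases_", ct)]] <- 0L
  if (total > 0) {
    tab <- table(factor(patients$tract_id, levels = tracts$tract_id),
                 factor(patients$category, levels = cats))
    for (ct in cats)
      out[[paste0("cases_", ct)]] <- as.integer(tab[, ct])
  }
  attr(out, "truth") <- list(S = S, eta = eta, gamma = gamma,
                             log_rate = log_rate, years = years,
                             counts_by_year = counts, params = truth)
  class(out) <- c("tract_table", "data.frame")
  list(tracts = out, patients = patients)
}

#' Thin patient records by the observation (selection) process
#'
#' Flags each patient as observed with probability
#' `plogis(intercept + dist_coeff * dist_centre + frailty_coeff * frailty)`
#' of their census tract.  With `frailty_coeff != 0` the observation
#' probability is correlated with the tract's unobserved risk and selection
#' is endogenous.
#'
#' @param patients patient records from [simulate_disease()].
#' @param tracts the matching `tract_table` (needs `dist_centre`).
#' @param sel a [selection_params()] object.
#' @param latent_frailty per-tract latent frailty vector aligned with
#'   `tracts`; defaults to the simulated spatial field plus iid
#'   heterogeneity stored in `attr(tracts, "truth")`.
#' @param seed integer seed.
#' @return `patients` with the `observed` flag filled in; the per-tract
#'   observation probabilities are attached as `attr(, "obs_prob")`.
#' @export
apply_selection <- function(patients, tracts, sel, latent_frailty = NULL,
                            seed = 1L) {
  stopifnot(inherits(sel, "selection_params"),
            "dist_centre" %in% names(tracts))
  if (is.null(latent_frailty)) {
    tru <- attr(tracts, "truth")
    latent_frailty <- if (!is.null(tru)) tru$S + tru$eta else
      numeric(nrow(tracts))
  }
  if (length(latent_frailty) != nrow(tracts))
    stop("apply_selection: 'latent_frailty' must align with 'tracts' (",
         length(latent_frailty), " vs ", nrow(tracts), ")")
  p <- stats::plogis(sel$intercept + sel$dist_coeff * tracts$dist_centre +
                       sel$frailty_coeff * latent_frailty)
  names(p) <- tracts$tract_id
  set.seed(seed)
  if (nrow(patients) > 0) {
    pt <- p[match(patients$tract_id, tracts$tract_id)]
    if (anyNA(pt)) stop("apply_selection: patients reference unknown tracts")
    patients$observed <- stats::runif(nrow(patients)) < pt
  }
  attr(patients, "obs_prob") <- p
  patients
}

#' Tract(-year) case counts from patient records
#'
#' @param patients patient records.
#' @param tracts the `tract_table` defining the row order.
#' @param category one of "MND" (all categories), "ALS", "PMA", "PLS".
#' @param years optional integer vector; when given, returns a tracts x
#'   years count matrix instead of per-tract totals.
#' @param observed_only count only records with `observed = TRUE`.
#' @return Integer vector (or matrix) of case counts.
#' @export
tract_case_counts <- function(patients, tracts, category = "MND",
                              years = NULL, observed_only = TRUE) {
  stopifnot(category %in% c("MND", "ALS", "PMA", "PLS"))
  keep <- rep(TRUE, nrow(patients))
  if (observed_only) keep <- keep & patients$observed
  if (category != "MND") keep <- keep & patients$category == category
  pp <- patients[keep, , drop = FALSE]
  fid <- factor(pp$tract_id, levels = tracts$tract_id)
  if (is.null(years)) {
    out <- as.integer(table(fid))
    names(out) <- tracts$tract_id
  } else {
    out <- table(fid, factor(pp$year, levels = years))
    out <- matrix(as.integer(out), nrow = nrow(tracts),
                  dimnames = list(tracts$tract_id, years))
  }
  out
}
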