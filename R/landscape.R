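# Synthetic two-region census-tract landscapes.
#
# The generator emulates the statistical structure of Spanish census-tract
# data: log-normal tract populations with median ~1,400 inhabitants, six
# sex-by-age population strata in fixed proportions, a deprivation gradient,
# and one referral centre per region at the population-weighted centroid.
# Geometry is planar (km) on two disjoint square patches; the Matern
# covariance consumes only Euclidean distance, so no real cartographic
# reference system is needed.

# fixed sex-by-age composition (shares of total population), close to the
# 2011 Spanish census structure: ~16% under 16, ~67% 16-64, ~17% 65+
.strata_props <- c(men_under16   = 0.0835, men_16to64   = 0.3392,
                   men_65plus    = 0.0742, women_under16 = 0.0785,
                   women_16to64  = 0.3293, women_65plus  = 0.0953)

.region_patch <- function(region) {
  # disjoint 60 x 60 km patches
  if (region == "A") c(x0 = 0, x1 = 60, y0 = 0, y1 = 60)
  else c(x0 = 100, x1 = 160, y0 = 0, y1 = 60)
}

#' Generate a synthetic two-region census-tract landscape
#'
#' Produces one row per census tract across two regions (`A` and `B`) laid
#' out on disjoint planar patches, with log-normal total populations
#' (median about 1,400, the Spanish census-tract norm), six sex-by-age
#' population strata drawn from fixed proportions, a spatially graded
#' deprivation score with its per-region quintile coding, and the distance
#' of each tract to its region's referral centre (the population-weighted
#' centroid, where the referral disease unit is assumed to sit).
#'
#' @param n_tracts_per_region number of tracts in each region, >= 4.
#' @param seed integer seed; output is deterministic given the seed.
#' @param pop_median median tract population of the log-normal law.
#' @param pop_sdlog log-scale standard deviation of tract populations.
#' @return A `data.frame` of class `tract_table` with columns `tract_id`,
#'   `region`, `x`, `y`, `pop_total`, `pop_over16`, the six stratum counts,
#'   `deprivation`, `deprivation_q` and `dist_centre` (km).  The referral
#'   centre coordinates are stored in `attr(, "referral_centres")`.
#' @examples
#' tr <- generate_landscape(50, seed = 1)
#' table(tr$region)
#' @export
generate_landscape <- function(n_tracts_per_region, seed,
                               pop_median = 1400, pop_sdlog = 0.45) {
  if (!is.numeric(n_tracts_per_region) || length(n_tracts_per_region) != 1L ||
      n_tracts_per_region < 4 ||
      n_tracts_per_region != round(n_tracts_per_region))
    stop("generate_landscape: 'n_tracts_per_region' must be an integer >= 4")
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(seed)
  n <- as.integer(n_tracts_per_region)

  per_region <- lapply(c("A", "B"), function(reg) {
    patch <- .region_patch(reg)
    x <- stats::runif(n, patch["x0"], patch["x1"])
    y <- stats::runif(n, patch["y0"], patch["y1"])
    pop <- pmax(50L, as.integer(round(stats::rlnorm(n, log(pop_median),
                                                    pop_sdlog))))
    strata <- t(vapply(pop, function(p)
      as.integer(stats::rmultinom(1, p, .strata_props)),
      integer(length(.strata_props))))
    colnames(strata) <- names(.strata_props)
    # deprivation: smooth west-east gradient plus tract-level noise,
    # standardised within region
    dep_raw <- (x - mean(x)) / (diff(range(x)) / 2) + stats::rnorm(n, 0, 0.6)
    dep <- as.vector(scale(dep_raw))
    df <- data.frame(
      tract_id = sprintf("%s%05d", reg, seq_len(n)),
      region = reg, x = x, y = y,
      pop_total = pop,
      pop_over16 = as.integer(strata[, "men_16to64"] + strata[, "men_65plus"] +
                              strata[, "women_16to64"] + strata[, "women_65plus"]),
      stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(strata))
    df$deprivation <- dep
    df$deprivation_q <- quintile_categorise(dep)
    cx <- sum(df$x * df$pop_total) / sum(df$pop_total)
    cy <- sum(df$y * df$pop_total) / sum(df$pop_total)
    df$dist_centre <- sqrt((df$x - cx)^2 + (df$y - cy)^2)
    list(df = df, centre = c(x = cx, y = cy))
  })

  out <- rbind(per_region[[1]]$df, per_region[[2]]$df)
  rownames(out) <- NULL
  attr(out, "referral_centres") <- list(A = per_region[[1]]$centre,
                                        B = per_region[[2]]$centre)
  class(out) <- c("tract_table", "data.frame")
  out
}

#' Generate socioeconomic indicator columns for a tract table
#'
#' Builds a tracts x 10 indicator matrix for the deprivation-index
#' procedure.  `n_loading` indicators load on a single latent deprivation
#' factor (the standardised `deprivation` column of the landscape) with
#' loadings drawn in \[0.7, 0.9\]; the remaining `n_noise` indicators are
#' independent standard-normal noise.  The latent factor and the names of
#' the signal columns are stored as attributes so index-recovery can be
#' tested.
#'
#' @param tracts a `tract_table`.
#' @param n_loading number of signal indicators; `n_loading + n_noise`
#'   must equal 10.
#' @param n_noise number of pure-noise indicators.
#' @param seed integer seed.
#' @return Numeric matrix (tracts x 10) with indicator names as column
#'   names and `tract_id` row names; attributes `latent_factor`,
#'   `signal_indicators`, `loadings`.
#' @export
generate_indicators <- function(tracts, n_loading = 6L, n_noise = 4L, seed = 1L) {
  stopifnot(inherits(tracts, "data.frame"), "deprivation" %in% names(tracts))
  if (n_loading + n_noise != 10L)
    stop("generate_indicators: 'n_loading' + 'n_noise' must equal 10")
  if (n_loading < 1L)
    stop("generate_indicators: need at least one loading indicator")
  set.seed(seed)
  nms <- c("p_unemployed", "p_manual_workers", "p_temporary_work",
           "p_no_schooling", "p_no_internet", "p_single_parent",
           "p_migrant_recent", "p_migrant_family", "p_over65",
           "p_secondary_homes")
  n <- nrow(tracts)
  f <- as.vector(scale(tracts$deprivation))
  loadings <- stats::runif(n_loading, 0.7, 0.9)
  M <- matrix(NA_real_, n, 10L, dimnames = list(tracts$tract_id, nms))
  for (j in seq_len(n_loading))
    M[, j] <- loadings[j] * f + sqrt(1 - loadings[j]^2) * stats::rnorm(n)
  if (n_noise > 0L)
    for (j in (n_loading + 1L):10L) M[, j] <- stats::rnorm(n)
  attr(M, "latent_factor") <- f
  attr(M, "signal_indicators") <- nms[seq_len(n_loading)]
  attr(M, "loadings") <- stats::setNames(loadings, nms[seq_len(n_loading)])
  M
}
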