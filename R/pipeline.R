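# End-to-end orchestration: simulate -> fit -> estimate -> pool, with
# deterministic per-stage seeds, a replicated simulation-study driver and a
# small command-line interface.

# deterministic per-stage, per-replicate seed derivation from a master
# seed: documented counter scheme, kept below 2^31
.stage_codes <- c(landscape = 1L, indicators = 2L, disease = 3L,
                  selection = 4L, fit = 5L, draws = 6L)

#' Derive a stage seed from a master seed
#'
#' `seed = (master * 1000 + stage_code * 101 + replicate) mod (2^31 - 1)`.
#' Stages: landscape 1, indicators 2, disease 3, selection 4, fit 5,
#' draws 6.  Replicates are independent yet fully reproducible from the
#' master seed.
#'
#' @param master master seed (integer).
#' @param stage stage name (see above).
#' @param replicate replicate number (>= 1).
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage, replicate = 1L) {
  code <- .stage_codes[[match.arg(stage, names(.stage_codes))]]
  as.integer((as.numeric(master) * 1000 + code * 101 + replicate) %%
               (2^31 - 1))
}

#' Run configuration for the simulation pipeline
#'
#' Bundles everything a full run needs; serialises losslessly through JSON
#' ([config_to_json()] / [config_from_json()]).
#'
#' @param seed master seed.
#' @param n_tracts_per_region landscape size per region.
#' @param years study period (calendar years).
#' @param base_rate,rw1_sd,eta_sd,beta passed to [truth_params()].
#' @param matern_sigma2,matern_range spatial-field truth.
#' @param sel_intercept,sel_dist_coeff,sel_frailty_coeff passed to
#'   [selection_params()].
#' @param spec a [two_part_spec()] for the fit stage.
#' @param chains,n_draws,outer_maxit engine settings.
#' @param out_dir output directory (created on demand).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_tracts_per_region = 100L,
                       years = 2013:2018,
                       base_rate = 2.0, rw1_sd = 0.05, eta_sd = 0,
                       beta = default_truth_beta(),
                       matern_sigma2 = 0.09, matern_range = 15,
                       sel_intercept = stats::qlogis(0.95),
                       sel_dist_coeff = -0.115, sel_frailty_coeff = 0,
                       spec = two_part_spec(),
                       chains = 2L, n_draws = 500L, outer_maxit = 60L,
                       out_dir = tempfile("mndrates_run_")) {
  structure(list(seed = as.integer(seed),
                 n_tracts_per_region = as.integer(n_tracts_per_region),
                 years = as.integer(years), base_rate = base_rate,
                 rw1_sd = rw1_sd, eta_sd = eta_sd, beta = beta,
                 matern_sigma2 = matern_sigma2, matern_range = matern_range,
                 sel_intercept = sel_intercept,
                 sel_dist_coeff = sel_dist_coeff,
                 sel_frailty_coeff = sel_frailty_coeff,
                 spec = spec, chains = as.integer(chains),
                 n_draws = as.integer(n_draws),
                 outer_maxit = as.integer(outer_maxit),
                 out_dir = out_dir),
            class = "run_config")
}

.cfg_truth <- function(cfg) {
  truth_params(
    base_rate = cfg$base_rate, beta = cfg$beta,
    matern = if (cfg$matern_sigma2 > 0)
      matern_params_from_range(cfg$matern_sigma2, cfg$matern_range,
                               nu = cfg$spec$nu) else NULL,
    rw1_sd = cfg$rw1_sd, eta_sd = cfg$eta_sd,
    selection = selection_params(cfg$sel_intercept, cfg$sel_dist_coeff,
                                 cfg$sel_frailty_coeff))
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path optional file path.
#' @export
config_to_json <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  x <- unclass(cfg)
  x$beta <- as.list(cfg$beta)   # keep names through JSON
  x$spec <- jsonlite::fromJSON(spec_to_json(cfg$spec))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname run_config
#' @param json JSON string or file path.
#' @export
config_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  x <- jsonlite::fromJSON(paste(json, collapse = "\n"))
  spec <- spec_from_json(jsonlite::toJSON(x$spec, auto_unbox = TRUE,
                                          null = "null", digits = NA))
  run_config(seed = x$seed, n_tracts_per_region = x$n_tracts_per_region,
             years = x$years, base_rate = x$base_rate, rw1_sd = x$rw1_sd,
             eta_sd = x$eta_sd, beta = unlist(x$beta),
             matern_sigma2 = x$matern_sigma2, matern_range = x$matern_range,
             sel_intercept = x$sel_intercept,
             sel_dist_coeff = x$sel_dist_coeff,
             sel_frailty_coeff = x$sel_frailty_coeff,
             spec = spec, chains = x$chains, n_draws = x$n_draws,
             outer_maxit = x$outer_maxit, out_dir = x$out_dir)
}

# one replicate: simulate -> (select) -> fit -> estimate; returns a row of
# study metrics plus the fixed-effect coverage flags
.run_replicate <- function(cfg, rep, region = "A") {
  tr <- generate_landscape(cfg$n_tracts_per_region,
                           seed = derive_seed(cfg$seed, "landscape", rep))
  tr <- tr[tr$region == region, , drop = FALSE]
  truth <- .cfg_truth(cfg)
  sim <- simulate_disease(tr, truth, cfg$years,
                          seed = derive_seed(cfg$seed, "disease", rep))
  use_sel <- cfg$spec$selection
  if (use_sel) {
    pats <- apply_selection(sim$patients, sim$tracts, truth$selection,
                            seed = derive_seed(cfg$seed, "selection", rep))
    ycounts <- tract_case_counts(pats, sim$tracts)
  } else {
    pats <- sim$patients
    ycounts <- sim$tracts$cases_MND
  }
  tru <- attr(sim$tracts, "truth")
  n_i <- pmax(1L, sim$tracts$pop_over16)
  W <- length(cfg$years)
  true_rate_py <- 1e5 * sum(n_i * exp(tru$log_rate)) *
    mean(exp(tru$gamma)) / sum(n_i)
  true_prev <- true_rate_py * W

  if (cfg$spec$target == "incidence")
    ycounts <- if (use_sel)
      tract_case_counts(pats, sim$tracts, years = cfg$years)
    else tru$counts_by_year

  fit <- suppressWarnings(fit_two_part(
    sim$tracts, ycounts, cfg$spec, years = cfg$years, chains = cfg$chains,
    n_draws = cfg$n_draws, seed = derive_seed(cfg$seed, "fit", rep),
    control = list(outer_maxit = cfg$outer_maxit)))

  est <- if (cfg$spec$target == "prevalence") region_prevalence(fit)
         else region_incidence(fit)
  truth_target <- if (cfg$spec$target == "prevalence") true_prev
                  else true_rate_py
  crude <- crude_rate_interval(
    sum(ycounts),
    if (cfg$spec$target == "prevalence") sum(n_i) else NULL,
    person_years = if (cfg$spec$target == "incidence") W * sum(n_i) else NULL)

  truth_b <- c(intercept = log(cfg$base_rate / 1e5),
               stats::setNames(numeric(length(cfg$spec$fixed_effects)),
                               cfg$spec$fixed_effects))
  known <- intersect(names(cfg$beta), names(truth_b))
  truth_b[known] <- truth_b[known] + cfg$beta[known]
  beta_cover <- vapply(names(truth_b), function(nm) {
    ps <- posterior_summary(fit, paste0("beta:", nm))
    ps$lower <= truth_b[[nm]] && truth_b[[nm]] <= ps$upper
  }, logical(1))

  list(metrics = data.frame(
         replicate = rep, true_rate = truth_target,
         est_point = est$point, est_lower = est$lower, est_upper = est$upper,
         est_covers = est$lower <= truth_target & truth_target <= est$upper,
         crude_point = crude$point, crude_lower = crude$lower,
         crude_upper = crude$upper,
         crude_covers = crude$lower <= truth_target &
           truth_target <= crude$upper,
         observed_fraction = if (use_sel) mean(pats$observed) else 1,
         converged = fit$converged),
       beta_cover = beta_cover)
}

#' Replicated simulation study
#'
#' Runs `n_replicates` independent simulate-fit-estimate replicates under a
#' [run_config()], reporting the coverage of the true rate by the corrected
#' 95% interval, the crude-rate comparison, bias, and per-coefficient
#' coverage of the fixed effects.  Replicate failures are recorded and the
#' study continues.  Artifacts (per-replicate metrics CSV, study summary
#' JSON) are written under `cfg$out_dir` when `write_artifacts = TRUE`.
#'
#' @param cfg a [run_config()].
#' @param n_replicates number of replicates.
#' @param write_artifacts write the report files under `cfg$out_dir`.
#' @return Object of class `study_report`: list with `metrics` (one row per
#'   successful replicate), `beta_coverage` (replicates x coefficients
#'   logical matrix), `summary` and `failures`.
#' @export
run_simulation_study <- function(cfg, n_replicates = 20L,
                                 write_artifacts = FALSE) {
  stopifnot(inherits(cfg, "run_config"), n_replicates >= 1L)
  rows <- list(); covers <- list(); failures <- list()
  for (r in seq_len(n_replicates)) {
    out <- tryCatch(.run_replicate(cfg, r), error = function(e) e)
    if (inherits(out, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(replicate = r, message = conditionMessage(out))
    } else {
      rows[[length(rows) + 1L]] <- out$metrics
      covers[[length(covers) + 1L]] <- out$beta_cover
    }
  }
  metrics <- do.call(rbind, rows)
  beta_cov <- if (length(covers)) do.call(rbind, covers) else NULL
  summary <- list(
    attempted = n_replicates,
    succeeded = length(rows),
    failed = length(failures),
    est_coverage = if (!is.null(metrics)) mean(metrics$est_covers) else NA,
    crude_coverage = if (!is.null(metrics)) mean(metrics$crude_covers) else NA,
    mean_rel_bias = if (!is.null(metrics))
      mean(metrics$est_point / metrics$true_rate - 1) else NA,
    beta_coverage = if (!is.null(beta_cov)) colMeans(beta_cov) else NULL)
  report <- structure(list(metrics = metrics, beta_coverage = beta_cov,
                           summary = summary,
                           failures = if (length(failures))
                             do.call(rbind, failures) else NULL,
                           config = cfg),
                      class = "study_report")
  if (write_artifacts) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(cfg$out_dir, "replicates.csv"),
                     row.names = FALSE)
    if (!is.null(beta_cov))
      utils::write.csv(as.data.frame(beta_cov),
                       file.path(cfg$out_dir, "beta_coverage.csv"),
                       row.names = FALSE)
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    config_to_json(cfg, file.path(cfg$out_dir, "config.json"))
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Simulation study: %d/%d replicates succeeded (%d failed)\n",
              s$succeeded, s$attempted, s$failed))
  cat(sprintf("  corrected 95%% interval coverage of truth: %.2f\n",
              s$est_coverage))
  cat(sprintf("  crude interval coverage of truth:        %.2f\n",
              s$crude_coverage))
  cat(sprintf("  mean relative bias of corrected point:   %+.3f\n",
              s$mean_rel_bias))
  invisible(x)
}

#' Pool published per-region estimates by interval intersection
#'
#' Reads a CSV of per-region rate estimates (columns `region`, `measure`,
#' `category`, `point`, `lower`, `upper`; two regions, both measures, all
#' four diagnostic categories) and pools each measure-category pair across
#' the two regions by credibility-interval intersection, formatted to three
#' decimals.
#'
#' @param estimates_csv path to the per-region estimates CSV, or a
#'   data frame.  The package ships a transcription of published two-region
#'   MND estimates under
#'   `system.file("extdata", "region_estimates.csv", package = "mndrates")`.
#' @param out_csv optional output path.
#' @return Data frame with one pooled row per measure-category pair.
#' @export
reproduce_paper_tables <- function(estimates_csv, out_csv = NULL) {
  df <- if (is.data.frame(estimates_csv)) estimates_csv
        else utils::read.csv(estimates_csv, stringsAsFactors = FALSE)
  need <- c("region", "measure", "category", "lower", "upper")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("reproduce_paper_tables: missing column(s): ",
         paste(miss, collapse = ", "))
  regions <- unique(df$region)
  if (length(regions) != 2L)
    stop("reproduce_paper_tables: need exactly 2 regions, found: ",
         paste(regions, collapse = ", "))
  out <- list()
  for (ms in c("prevalence", "incidence")) for (ct in c("MND", "ALS", "PMA",
                                                        "PLS")) {
    rows <- df[df$measure == ms & df$category == ct, , drop = FALSE]
    if (nrow(rows) != 2L)
      stop("reproduce_paper_tables: missing region row(s) for ",
           ms, "/", ct)
    a <- rows[1, ]; b <- rows[2, ]
    pooled <- pool_intervals(a, b)
    pooled$lower <- round(pooled$lower, 3)
    pooled$upper <- round(pooled$upper, 3)
    out[[paste(ms, ct)]] <- pooled
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(out_csv)) utils::write.csv(res, out_csv, row.names = FALSE)
  res
}

# ---- command-line interface -------------------------------------------

.cli_args <- function(args) {
  # --key value / --flag parsing
  out <- list(); i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
        out[[key]] <- args[[i + 1L]]; i <- i + 2L
      } else { out[[key]] <- TRUE; i <- i + 1L }
    } else i <- i + 1L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (landscape + disease + selection, writes tract /
#' patient CSVs and a GeoJSON), `deprivation` (indicator CSV to index CSV +
#' retained-set JSON), `fit` (tract CSV to fit summary JSON and RDS),
#' `estimate` (fit RDS to rates CSV), `pool` (estimates CSV to pooled CSV),
#' `study` (config JSON, replicated study), `reproduce-tables` (published
#' estimates CSV to pooled CSV).  Invoke via
#' `Rscript -e 'mndrates::mnd_cli()' <subcommand> --key value ...`
#' Common options: `--seed`, `--out` (output directory), `--n-tracts`,
#' `--replicates`, `--config`, `--input`.
#'
#' @param args character vector of CLI arguments (defaults to the command
#'   line).
#' @return Invisibly, the primary result object of the subcommand.
#' @export
mnd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: mnd_cli <simulate|deprivation|fit|estimate|pool|study|",
        "reproduce-tables> [--seed N] [--out DIR] ...\n", sep = "")
    return(invisible(NULL))
  }
  cmd <- args[[1]]
  opt <- .cli_args(args[-1])
  seed <- as.integer(opt$seed %||% 1L)
  out_dir <- opt$out %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  res <- switch(
    cmd,
    simulate = {
      n <- as.integer(opt[["n-tracts"]] %||% 100L)
      cfg <- run_config(seed = seed, n_tracts_per_region = n,
                        sel_frailty_coeff =
                          as.numeric(opt[["frailty-coeff"]] %||% 0))
      tr <- generate_landscape(n, seed = derive_seed(seed, "landscape"))
      truth <- .cfg_truth(cfg)
      sim <- simulate_disease(tr, truth, cfg$years,
                              seed = derive_seed(seed, "disease"))
      pats <- apply_selection(sim$patients, sim$tracts, truth$selection,
                              seed = derive_seed(seed, "selection"))
      write_tract_table(sim$tracts, file.path(out_dir, "tracts.csv"))
      write_patient_records(pats, file.path(out_dir, "patients.csv"))
      tracts_geojson(sim$tracts, file.path(out_dir, "tracts.geojson"))
      sim
    },
    deprivation = {
      ind <- utils::read.csv(opt$input, stringsAsFactors = FALSE)
      res <- sequential_pca_index(ind)
      q <- quintile_categorise(res$index)
      utils::write.csv(
        data.frame(tract_id = names(res$index), index = res$index,
                   quintile = q),
        file.path(out_dir, "deprivation_index.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(retained = res$retained,
             correlations = as.list(res$correlations)),
        file.path(out_dir, "deprivation_retained.json"), auto_unbox = TRUE)
      res
    },
    fit = {
      tr <- read_tract_table(opt$input)
      counts <- tr[[paste0("cases_", opt$response %||% "MND")]]
      spec <- if (!is.null(opt$spec)) spec_from_json(opt$spec)
              else two_part_spec()
      fit <- fit_two_part(tr, counts, spec,
                          years = seq_len(as.integer(opt$window %||% 6L)),
                          seed = derive_seed(seed, "fit"))
      saveRDS(fit, file.path(out_dir, "fit.rds"))
      jsonlite::write_json(
        list(hyper = fit$hyper, converged = fit$converged,
             diagnostics = fit$diagnostics,
             beta = lapply(as.data.frame(fit$draws$beta),
                           function(b) posterior_summary(b))),
        file.path(out_dir, "fit_summary.json"), auto_unbox = TRUE,
        digits = NA)
      fit
    },
    estimate = {
      fit <- readRDS(opt$input)
      est <- if (fit$spec$target == "prevalence") region_prevalence(fit)
             else region_incidence(fit)
      tr_est <- tract_rates(fit)
      write_rate_estimates(est, file.path(out_dir, "region_estimate.csv"))
      write_rate_estimates(tr_est, file.path(out_dir, "tract_rates.csv"))
      est
    },
    pool = {
      df <- utils::read.csv(opt$input, stringsAsFactors = FALSE)
      res <- reproduce_paper_tables(df, file.path(out_dir, "pooled.csv"))
      res
    },
    study = {
      cfg <- if (!is.null(opt$config)) config_from_json(opt$config)
             else run_config(seed = seed)
      cfg$out_dir <- out_dir
      run_simulation_study(cfg,
                           n_replicates = as.integer(opt$replicates %||% 5L),
                           write_artifacts = TRUE)
    },
    "reproduce-tables" = {
      reproduce_paper_tables(opt$input, file.path(out_dir, "pooled.csv"))
    },
    stop("mnd_cli: unknown subcommand '", cmd, "'"))
  log <- list(command = cmd, seed = seed,
              wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                units = "secs")),
              package_version = as.character(utils::packageVersion("mndrates")))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
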