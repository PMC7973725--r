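# Joint Bayesian fit of the two-part model.
#
# Engine: a nested Laplace approximation with empirical-Bayes
# hyperparameters.  For fixed hyperparameters phi (random-effect sds,
# spatial range, zero-inflation mass, selection loading) the latent vector
# z -- fixed effects, selection distance coefficient, iid heterogeneity,
# spatial field, RW1 year effects -- is maximised by damped Newton with
# exact curvature (projected to positive definite where the ZIP zero mass
# makes the likelihood locally non-concave).  phi is then optimised on the
# Laplace-approximate marginal posterior, and posterior draws of z are
# taken from the Gaussian approximation at the joint mode.  Draws are
# therefore independent; MCMC-style diagnostics (split-chain R-hat,
# effective sample size) are still computed and reported, as the contract
# requires them for every scalar parameter.
#
# The likelihood is the composite specified for the model: a binomial
# observation part (trials = population at risk) plus a zero-inflated
# Poisson count part, sharing the disease surface and the spatial field,
# with the selection (observation) probability entering part 2 as a
# log-probability offset (thinned-count formulation) or, behind a flag, as
# inverse-probability weights on the part-2 likelihood terms.

# ---- likelihood channel derivatives -----------------------------------

# per-cell derivatives of the channel log-likelihood wrt the log-mean u
.chan_derivs <- function(ch, u, pi0, w = NULL) {
  if (ch$type == "zip") {
    theta <- exp(u)
    l <- zip_logpmf(ch$y, theta, pi0)
    g <- h <- numeric(length(u))
    pos <- ch$y > 0
    g[pos] <- ch$y[pos] - theta[pos]
    h[pos] <- -theta[pos]
    if (any(!pos)) {
      th <- theta[!pos]
      if (pi0 > 0) {
        la <- log1p(-pi0) - th
        lb <- log(pi0)
        m <- pmax(la, lb)
        wz <- exp(la - m) / (exp(la - m) + exp(lb - m))   # A/B
      } else wz <- rep(1, length(th))
      g[!pos] <- -th * wz
      h[!pos] <- -th * wz + th^2 * wz * (1 - wz)
    }
  } else {                                   # binomial, logit(P) = u - log n
    v <- u - log(ch$trials)
    P <- stats::plogis(v)
    l <- stats::dbinom(ch$y, ch$trials, P, log = TRUE)
    g <- ch$y - ch$trials * P
    h <- -ch$trials * P * (1 - P)
  }
  if (!is.null(w)) { l <- w * l; g <- w * g; h <- w * h }
  list(l = sum(l), g = g, h = h)
}

# objective, gradient and (projected) negative Hessian over channels
.joint_eval <- function(z, channels, Q, pi0, sel, need_hess = TRUE) {
  m <- length(z)
  obj <- -0.5 * sum(z * (Q %*% z))
  g <- -as.vector(Q %*% z)
  H <- if (need_hess) Q else NULL
  for (ch in channels) {
    u <- ch$offset + as.vector(ch$A %*% z)
    omp <- NULL
    if (!is.null(ch$As)) {                       # selection: u += log p(s)
      s <- ch$s_off + as.vector(ch$As %*% z)
      p <- stats::plogis(s)
      u <- u + log(p)
      omp <- 1 - p
    }
    d <- .chan_derivs(ch, u, if (ch$type == "zip") pi0 else 0, ch$w)
    obj <- obj + d$l
    if (is.null(ch$As)) {
      g <- g + as.vector(crossprod(ch$A, d$g))
      if (need_hess) H <- H + crossprod(ch$A, pmax(-d$h, 1e-12) * ch$A)
    } else {
      J <- ch$A + omp * ch$As
      g <- g + as.vector(crossprod(J, d$g))
      if (need_hess) {
        H <- H + crossprod(J, pmax(-d$h, 1e-12) * J)
        # curvature of log p(s): d2u/ds2 = -p(1-p); PSD projection
        w2 <- pmax(d$g * (1 - omp) * omp, 0)
        H <- H + crossprod(ch$As, w2 * ch$As)
      }
    }
  }
  list(obj = obj, g = g, H = H)
}

.newton <- function(z0, channels, Q, pi0, max_iter = 40, tol = 1e-7) {
  z <- z0
  ev <- .joint_eval(z, channels, Q, pi0)
  for (it in seq_len(max_iter)) {
    R <- tryCatch(chol(ev$H), error = function(e) NULL)
    if (is.null(R)) {
      R <- chol(ev$H + diag(1e-6 * max(diag(ev$H)), length(z)))
    }
    delta <- backsolve(R, backsolve(R, ev$g, transpose = TRUE))
    step <- 1
    repeat {
      z_new <- z + step * delta
      ev_new <- .joint_eval(z_new, channels, Q, pi0, need_hess = FALSE)
      if (is.finite(ev_new$obj) && ev_new$obj >= ev$obj - 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    improved <- is.finite(ev_new$obj) && ev_new$obj > ev$obj
    z <- if (improved || ev_new$obj >= ev$obj) z_new else z
    ev_full <- .joint_eval(z, channels, Q, pi0)
    converged <- max(abs(ev_full$g)) < tol * (1 + abs(ev_full$obj)) ||
      abs(ev_full$obj - ev$obj) < 1e-9 * (1 + abs(ev$obj))
    ev <- ev_full
    if (converged) break
  }
  R <- tryCatch(chol(ev$H), error = function(e)
    chol(ev$H + diag(1e-6 * max(diag(ev$H)), length(z))))
  list(z = z, obj = ev$obj, g = ev$g, R = R,
       logdet = 2 * sum(log(diag(R))),
       converged = max(abs(ev$g)) < 1e-3 * (1 + abs(ev$obj)))
}

# ---- diagnostics ------------------------------------------------------

.split_rhat <- function(x, n_chains) {
  n <- length(x)
  per <- floor(n / (2 * n_chains))
  if (per < 2L) return(NA_real_)
  M <- matrix(x[seq_len(per * 2 * n_chains)], nrow = per)
  mns <- colMeans(M); vrs <- apply(M, 2, stats::var)
  W <- mean(vrs); B <- per * stats::var(mns)
  if (W <= 0) return(1)
  sqrt(((per - 1) / per * W + B / per) / W)
}

.ess_basic <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) { if (r < 0.05) break; s <- s + r }
  max(1, n / (1 + 2 * s))
}

# ---- main fit ---------------------------------------------------------

#' Fit the two-part model jointly
#'
#' Fits both parts of the hurdle model -- binomial observation part and
#' zero-inflated Poisson count part -- jointly by a nested Laplace
#' approximation (see the package vignette for the engine's assumptions).
#' Returns posterior draws for the fixed effects, selection parameters,
#' latent fields and derived log rates, with empirical-Bayes point
#' estimates of the hyperparameters.
#'
#' @param tracts a `tract_table` (needs population strata, deprivation
#'   quintiles and, when the spec includes selection, `dist_centre`).
#' @param counts observed case counts: a per-tract vector for prevalence
#'   specs, or a tracts x years matrix for incidence specs.
#' @param spec a [two_part_spec()].
#' @param years calendar years spanned by `counts` (the study window).  For
#'   a prevalence spec only its length is used (window size in years).
#' @param chains number of independent draw batches used for diagnostics
#'   (>= 2).
#' @param n_draws posterior draws per chain.
#' @param seed integer seed controlling the posterior draws.
#' @param control list of engine knobs: `outer_maxit` (Nelder-Mead
#'   iterations over hyperparameters, default 80), `outer_reltol` (default
#'   1e-5), `verbose`.
#' @return Object of class `two_part_fit` with elements `draws` (matrices
#'   of posterior draws: `beta`, `dist_coeff`, `eta2`, `S`, `gamma`,
#'   `log_rate`, `obs_logit`), `hyper` (empirical-Bayes hyperparameter
#'   estimates), `diagnostics` (R-hat and ESS per scalar parameter),
#'   `converged`, `spec`, `seed` and the data summaries needed by the rate
#'   estimators.  Non-convergence yields a warning, never an error.
#' @export
fit_two_part <- function(tracts, counts, spec, years = NULL, chains = 2L,
                         n_draws = 1000L, seed = 1L, control = list()) {
  stopifnot(inherits(spec, "two_part_spec"), chains >= 2L, n_draws >= 10L)
  ctl <- utils::modifyList(list(outer_maxit = 80L, outer_reltol = 1e-5,
                                verbose = FALSE), control)
  n <- nrow(tracts)
  trials <- pmax(1L, tracts$pop_over16)

  if (spec$target == "incidence") {
    if (!is.matrix(counts)) stop("fit_two_part: incidence specs need a ",
                                 "tracts x years count matrix")
    if (is.null(years)) years <- as.integer(colnames(counts))
    Tn <- ncol(counts)
    if (Tn < 2L) stop("fit_two_part: incidence needs >= 2 years")
    y <- as.vector(counts)
    cell_tract <- rep(seq_len(n), Tn)
    cell_year <- rep(seq_len(Tn), each = n)
    cell_off <- log(trials)[cell_tract]
    W <- Tn
  } else {
    if (is.matrix(counts)) counts <- rowSums(counts)
    if (length(counts) != n) stop("fit_two_part: counts/tracts mismatch")
    W <- if (is.null(years)) 1L else length(years)
    Tn <- 0L
    y <- counts
    cell_tract <- seq_len(n)
    cell_year <- integer(length(y))
    cell_off <- log(trials) + log(W)
  }
  if (any(y < 0) || any(y != round(y)))
    stop("fit_two_part: counts must be nonnegative integers")

  Xall <- tract_design(tracts)
  bad <- setdiff(spec$fixed_effects, colnames(Xall))
  if (length(bad)) stop("fit_two_part: unknown fixed effect(s): ",
                        paste(bad, collapse = ", "))
  X <- Xall[, spec$fixed_effects, drop = FALSE]
  k <- ncol(X)
  use_sel <- spec$coupled && spec$selection
  if (use_sel && !"dist_centre" %in% names(tracts))
    stop("fit_two_part: selection spec needs a 'dist_centre' column")
  use_eta <- spec$coupled && spec$heterogeneity
  use_S <- spec$coupled && spec$spatial
  use_rw <- spec$temporal_rw1 && Tn >= 2L
  use_zip <- "zip" %in% spec$parts
  use_binom <- "binomial" %in% spec$parts
  ipw <- use_sel && spec$weighting_rule == "likelihood_weight"
  a0 <- stats::qlogis(spec$coverage_at_centre)

  # ---- latent vector layout
  idx <- list(); m <- 0L
  push <- function(name, len) {
    if (len > 0L) { idx[[name]] <<- m + seq_len(len); m <<- m + len }
  }
  if (spec$coupled) {
    push("b", k + 1L)                       # intercept + fixed effects
    if (use_sel) push("a_d", 1L)
    if (use_eta) push("eta2", n)
    if (use_S) push("S", n)
    if (use_rw) push("gamma", Tn)
  } else {
    if (use_binom) push("b1", k + 1L)
    if (use_zip) push("b2", k + 1L)
  }

  coords <- cbind(tracts$x, tracts$y)
  diam <- sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))
  pr <- spec$priors
  range_u <- if (is.null(pr$range_u)) 0.1 * max(diam, 1e-6) else pr$range_u

  # ---- design maps (cells x m)
  ncell <- length(y)
  A <- matrix(0, ncell, m)
  fill_block <- function(A, cols, M) { A[, cols] <- M; A }
  ones <- rep(1, ncell)
  Xcell <- X[cell_tract, , drop = FALSE]
  if (spec$coupled) {
    A[, idx$b] <- cbind(ones, Xcell)
    if (use_eta) A[cbind(seq_len(ncell), idx$eta2[cell_tract])] <- 1
    if (use_S) A[cbind(seq_len(ncell), idx$S[cell_tract])] <-
        A[cbind(seq_len(ncell), idx$S[cell_tract])] + 1
    if (use_rw) A[cbind(seq_len(ncell), idx$gamma[cell_year])] <- 1
  }

  make_channels <- function(c_s) {
    chans <- list()
    As <- NULL; s_off <- NULL
    if (use_sel) {
      As <- matrix(0, ncell, m)
      As[, idx$a_d] <- tracts$dist_centre[cell_tract]
      if (use_S && c_s != 0)
        As[cbind(seq_len(ncell), idx$S[cell_tract])] <- c_s
      s_off <- rep(a0, ncell)
    }
    if (spec$coupled) {
      # composite-likelihood weighting: in the coupled model both parts are
      # link-scale views of the same counts; weighting each by 1/2 keeps the
      # total information per observation at one observation and prevents
      # the doubled residuals from masquerading as tract heterogeneity
      w_cl <- if (use_binom && use_zip) rep(0.5, ncell) else NULL
      if (use_binom)
        chans$binom <- list(type = "binom", y = y, trials = trials[cell_tract],
                            offset = cell_off, A = A,
                            As = As, s_off = s_off, w = w_cl)
      if (use_zip) {
        if (ipw)
          chans$zip <- list(type = "zip", y = y, trials = trials[cell_tract],
                            offset = cell_off, A = A, As = NULL, w = w_cl)
        else
          chans$zip <- list(type = "zip", y = y, trials = trials[cell_tract],
                            offset = cell_off, A = A,
                            As = As, s_off = s_off, w = w_cl)
      }
    } else {
      if (use_binom) {
        A1 <- matrix(0, ncell, m); A1[, idx$b1] <- cbind(ones, Xcell)
        chans$binom <- list(type = "binom", y = y, trials = trials[cell_tract],
                            offset = log(trials)[cell_tract], A = A1,
                            As = NULL, w = NULL)
      }
      if (use_zip) {
        A2 <- matrix(0, ncell, m); A2[, idx$b2] <- cbind(ones, Xcell)
        chans$zip <- list(type = "zip", y = y, trials = trials[cell_tract],
                          offset = cell_off, A = A2, As = NULL, w = NULL)
      }
    }
    chans
  }

  # ---- hyperparameter vector
  hyp_names <- character()
  if (use_eta) hyp_names <- c(hyp_names, "log_sigma_eta2")
  if (use_S) hyp_names <- c(hyp_names, "log_sigma_S", "log_range")
  if (use_zip && spec$estimate_pi0) hyp_names <- c(hyp_names, "logit_pi0")
  if (use_rw) hyp_names <- c(hyp_names, "log_sigma_rw")
  if (use_sel && spec$endogenous && use_S) hyp_names <- c(hyp_names, "c_s")
  phi0 <- stats::setNames(numeric(length(hyp_names)), hyp_names)
  if (use_eta) phi0["log_sigma_eta2"] <- log(0.3)
  if (use_S) { phi0["log_sigma_S"] <- log(0.3)
               phi0["log_range"] <- log(0.25 * max(diam, 1)) }
  if (use_zip && spec$estimate_pi0) phi0["logit_pi0"] <- stats::qlogis(0.05)
  if (use_rw) phi0["log_sigma_rw"] <- log(0.1)

  D <- as.matrix(stats::dist(coords))

  build_Q <- function(phi) {
    Q <- diag(1e-8, m)
    if (spec$coupled) {
      Q[idx$b, idx$b] <- diag(1e-2, k + 1L)
      if (use_sel) Q[idx$a_d, idx$a_d] <- 1e-2
      if (use_eta) {
        s2 <- exp(2 * phi[["log_sigma_eta2"]])
        Q[idx$eta2, idx$eta2] <- diag(1 / s2, n)
      }
      if (use_S) {
        mp <- matern_params_from_range(exp(2 * phi[["log_sigma_S"]]),
                                       exp(phi[["log_range"]]), nu = spec$nu)
        Sg <- matrix(matern_covariance(as.vector(D), mp), n, n)
        Qs <- chol2inv(chol(Sg + diag(1e-8 * mp$sigma2, n)))
        Q[idx$S, idx$S] <- Qs
      }
      if (use_rw) {
        tau <- exp(-2 * phi[["log_sigma_rw"]])
        Dd <- diff(diag(Tn))
        Q[idx$gamma, idx$gamma] <- tau * crossprod(Dd) +
          matrix(100 / Tn^2, Tn, Tn) + diag(1e-8, Tn)
      }
    } else {
      for (blk in intersect(c("b1", "b2"), names(idx)))
        Q[idx[[blk]], idx[[blk]]] <- diag(1e-2, k + 1L)
    }
    Q
  }

  log_prior_phi <- function(phi) {
    lp <- 0
    for (nm in c("log_sigma_eta2", "log_sigma_rw"))
      if (nm %in% hyp_names) {
        s <- exp(phi[[nm]])
        lp <- lp + pc_prior_sd_logdensity(s, pr$sd_u, pr$sd_alpha) + phi[[nm]]
      }
    if ("log_sigma_S" %in% hyp_names) {
      s <- exp(phi[["log_sigma_S"]])
      lp <- lp + pc_prior_sd_logdensity(s, pr$sd_u, pr$sd_alpha) +
        phi[["log_sigma_S"]]
      rho <- exp(phi[["log_range"]])
      lp <- lp + pc_prior_range_logdensity(rho, range_u, pr$range_alpha) +
        phi[["log_range"]]
    }
    if ("logit_pi0" %in% hyp_names) {
      p <- stats::plogis(phi[["logit_pi0"]])     # uniform(0,1) + Jacobian
      lp <- lp + log(p) + log1p(-p)
    }
    if ("c_s" %in% hyp_names)
      lp <- lp + stats::dnorm(phi[["c_s"]], 0, 2, log = TRUE)
    lp
  }

  z_warm <- numeric(m)
  b0_init <- log((sum(y) + 0.5) / sum(exp(cell_off))) -
    if (use_sel) log(mean(stats::plogis(a0 + 0 * trials))) else 0
  if (spec$coupled) z_warm[idx$b[1]] <- b0_init else {
    if (use_binom) z_warm[idx$b1[1]] <- stats::qlogis(
      min(0.4, (sum(y) + 0.5) / sum(trials[cell_tract])))
    if (use_zip) z_warm[idx$b2[1]] <- b0_init
  }

  inner <- function(phi) {
    pi0 <- if ("logit_pi0" %in% hyp_names) stats::plogis(phi[["logit_pi0"]])
           else 0
    c_s <- if ("c_s" %in% hyp_names) phi[["c_s"]] else 0
    chans <- make_channels(c_s)
    Q <- build_Q(phi)
    if (ipw) {
      # iteratively reweighted inverse-probability weighting on part 2
      fit <- NULL
      for (rep in 1:3) {
        if (!is.null(fit)) {
          s <- a0 + tracts$dist_centre[cell_tract] * fit$z[idx$a_d] +
            if (use_S && c_s != 0) c_s * fit$z[idx$S][cell_tract] else 0
          base_w <- if (use_binom && use_zip) 0.5 else 1
          chans$zip$w <- base_w / pmax(stats::plogis(s), 0.05)
        }
        fit <- .newton(z_warm, chans, Q, pi0)
        z_warm <<- fit$z
      }
    } else {
      fit <- .newton(z_warm, chans, Q, pi0)
      z_warm <<- fit$z
    }
    Rq <- chol(Q)
    list(fit = fit, pi0 = pi0, c_s = c_s, Q = Q,
         marg = fit$obj + sum(log(diag(Rq))) - 0.5 * fit$logdet +
           log_prior_phi(phi))
  }

  if (length(phi0)) {
    neg <- function(p) {
      names(p) <- hyp_names
      r <- tryCatch(inner(p)$marg, error = function(e) -Inf)
      if (!is.finite(r)) 1e10 else -r
    }
    opt <- if (length(phi0) == 1L)
      stats::optim(phi0, neg, method = "Brent", lower = phi0 - 6,
                   upper = phi0 + 6)
    else
      stats::optim(phi0, neg, method = "Nelder-Mead",
                   control = list(maxit = ctl$outer_maxit,
                                  reltol = ctl$outer_reltol))
    phi_hat <- stats::setNames(opt$par, hyp_names)
  } else phi_hat <- phi0
  sol <- inner(phi_hat)
  fit0 <- sol$fit
  if (!fit0$converged)
    warning("fit_two_part: inner optimisation did not fully converge; ",
            "results are returned but flagged")

  # ---- posterior draws (independent, per chain, from the Laplace Gaussian)
  set.seed(seed)
  total <- chains * n_draws
  Z <- matrix(stats::rnorm(m * total), m, total)
  draws_z <- fit0$z + backsolve(fit0$R, Z)     # m x total

  get_block <- function(name) {
    if (is.null(idx[[name]])) NULL else t(draws_z[idx[[name]], , drop = FALSE])
  }
  beta <- if (spec$coupled) get_block("b") else get_block("b2")
  if (!is.null(beta))
    colnames(beta) <- c("intercept", spec$fixed_effects)
  beta1 <- if (!spec$coupled) get_block("b1") else NULL
  if (!is.null(beta1)) colnames(beta1) <- c("intercept", spec$fixed_effects)
  eta2 <- get_block("eta2"); Sdr <- get_block("S"); gam <- get_block("gamma")
  a_d <- get_block("a_d")

  log_rate <- NULL
  if (spec$coupled && !is.null(beta)) {
    log_rate <- beta %*% t(cbind(1, X))
    if (!is.null(eta2)) log_rate <- log_rate + eta2
    if (!is.null(Sdr)) log_rate <- log_rate + Sdr
    colnames(log_rate) <- tracts$tract_id
  }
  obs_logit <- NULL
  if (use_sel) {
    obs_logit <- a0 + a_d %*% t(tracts$dist_centre)
    if (use_S && sol$c_s != 0 && !is.null(Sdr))
      obs_logit <- obs_logit + sol$c_s * Sdr
    colnames(obs_logit) <- tracts$tract_id
  }

  hyper <- list(
    sigma_eta2 = if (use_eta) exp(phi_hat[["log_sigma_eta2"]]) else NA_real_,
    sigma_S = if (use_S) exp(phi_hat[["log_sigma_S"]]) else NA_real_,
    range = if (use_S) exp(phi_hat[["log_range"]]) else NA_real_,
    pi0 = sol$pi0,
    sigma_rw = if (use_rw) exp(phi_hat[["log_sigma_rw"]]) else NA_real_,
    c_s = sol$c_s,
    coverage_at_centre = if (use_sel) spec$coverage_at_centre else NA_real_)

  scalars <- list()
  if (!is.null(beta)) for (j in colnames(beta))
    scalars[[paste0("beta:", j)]] <- beta[, j]
  if (!is.null(beta1)) for (j in colnames(beta1))
    scalars[[paste0("beta1:", j)]] <- beta1[, j]
  if (!is.null(a_d)) scalars[["dist_coeff"]] <- a_d[, 1]
  diag_tab <- data.frame(
    parameter = names(scalars),
    rhat = vapply(scalars, .split_rhat, 0, n_chains = chains),
    ess = vapply(scalars, .ess_basic, 0),
    row.names = NULL)
  converged <- fit0$converged &&
    all(is.na(diag_tab$rhat) | diag_tab$rhat <= 1.05)
  if (!converged && fit0$converged)
    warning("fit_two_part: diagnostics exceed the 1.05 threshold; ",
            "fit flagged as not converged")

  structure(list(
    draws = list(beta = beta, beta1 = beta1, dist_coeff = a_d, eta2 = eta2,
                 S = Sdr, gamma = gam, log_rate = log_rate,
                 obs_logit = obs_logit),
    hyper = hyper, diagnostics = diag_tab, converged = converged,
    spec = spec, seed = seed, chains = chains, n_draws = n_draws,
    marginal = sol$marg,
    data = list(tract_id = tracts$tract_id, region = tracts$region,
                pop_total = tracts$pop_total, pop_over16 = trials,
                window_years = W, years = years, counts = y,
                n_tracts = n)),
    class = "two_part_fit")
}

#' @export
print.two_part_fit <- function(x, ...) {
  cat(sprintf("Two-part model fit: %s %s, %d tracts, window %d year(s)\n",
              x$spec$response, x$spec$target, x$data$n_tracts,
              x$data$window_years))
  cat(sprintf("  converged: %s; hyper: sigma_eta2=%.3g sigma_S=%.3g range=%.3g pi0=%.3g c_s=%.3g\n",
              x$converged, x$hyper$sigma_eta2, x$hyper$sigma_S,
              x$hyper$range, x$hyper$pi0, x$hyper$c_s))
  invisible(x)
}

#' Posterior observation probabilities per tract
#'
#' Posterior mean and equal-tailed 95% interval of the inverse-logit part-1
#' (observation) predictor for every tract.  These are the probabilities
#' that weight the second part of the model.
#'
#' @param fit a `two_part_fit` from a spec with `selection = TRUE`.
#' @return `data.frame` with `tract_id`, `mean`, `lower`, `upper`.
#' @export
observation_weights <- function(fit) {
  stopifnot(inherits(fit, "two_part_fit"))
  if (is.null(fit$draws$obs_logit))
    stop("observation_weights: fit has no part-1 selection parameters")
  P <- stats::plogis(fit$draws$obs_logit)
  data.frame(tract_id = colnames(P),
             mean = colMeans(P),
             lower = apply(P, 2, stats::quantile, 0.025),
             upper = apply(P, 2, stats::quantile, 0.975),
             row.names = NULL)
}

#' Posterior point and interval summary
#'
#' Point estimate (posterior median) and equal-tailed 95% credibility
#' interval, either of a raw draw vector or of a named quantity of a
#' `two_part_fit` (`"beta:<name>"`, `"dist_coeff"`, or any column name of
#' the fixed-effect draws).
#'
#' @param x numeric draws, or a `two_part_fit`.
#' @param quantity quantity name when `x` is a fit.
#' @param ... unused.
#' @return List with `point`, `lower`, `upper`.
#' @export
posterior_summary <- function(x, ...) UseMethod("posterior_summary")

#' @rdname posterior_summary
#' @export
posterior_summary.numeric <- function(x, ...) {
  q <- unname(stats::quantile(x, c(0.5, 0.025, 0.975)))
  list(point = q[1], lower = q[2], upper = q[3])
}

#' @rdname posterior_summary
#' @export
posterior_summary.two_part_fit <- function(x, quantity, ...) {
  dr <- NULL
  if (quantity %in% names(x$draws) && is.matrix(x$draws[[quantity]]) &&
      ncol(x$draws[[quantity]]) == 1L) dr <- x$draws[[quantity]][, 1]
  if (is.null(dr) && grepl("^beta:", quantity)) {
    nm <- sub("^beta:", "", quantity)
    if (!is.null(x$draws$beta) && nm %in% colnames(x$draws$beta))
      dr <- x$draws$beta[, nm]
  }
  if (is.null(dr) && !is.null(x$draws$beta) &&
      quantity %in% colnames(x$draws$beta)) dr <- x$draws$beta[, quantity]
  if (is.null(dr)) stop("posterior_summary: unknown quantity '", quantity, "'")
  posterior_summary(dr)
}
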