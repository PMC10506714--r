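#' Model configuration
#'
#' @param variant `"m2"` (daily WT residuals regressed on covariate residuals,
#'   the default) or `"m1"` (daily WT residuals follow a zero-mean AR1 process).
#' @param use_discharge logical; `NA` (default) resolves to whether the dataset
#'   carries a discharge series.
#' @param shared_intercept if `TRUE` the window-maximum and window-minimum
#'   regressions share one intercept `theta0`; the default keeps two distinct
#'   intercepts `theta0` and `theta0p`.
#' @return list of class `stm_config`.
#' @export
stm_config <- function(variant = c("m2", "m1"), use_discharge = NA,
                       shared_intercept = FALSE) {
  variant <- match.arg(variant)
  structure(list(variant = variant, use_discharge = use_discharge,
                 shared_intercept = isTRUE(shared_intercept)),
            class = "stm_config")
}

#' MCMC settings
#'
#' Two presets are provided. `"desk"` (3 chains, burn-in 4000, 2000 kept per
#' chain, no thinning) is sized for interactive work and simulation
#' experiments; the burn-in is long enough for the phase parameters to merge
#' from overdispersed starts. `"paper"` (3 chains, burn-in 10000, thinning 25, 10000 kept per
#' chain) reproduces the heavy settings customarily used for a final fit.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param n_chains,n_burnin,n_keep,thin explicit overrides of the preset.
#' @param seed integer seed; every chain derives its RNG stream from it and a
#'   rerun with the same settings reproduces the draws bit-for-bit.
#' @return list of class `stm_mcmc`.
#' @export
stm_mcmc <- function(preset = c("desk", "paper"), n_chains = NULL, n_burnin = NULL,
                     n_keep = NULL, thin = NULL, seed = 1L) {
  preset <- match.arg(preset)
  def <- switch(preset,
                desk  = list(n_chains = 3L, n_burnin = 4000L, n_keep = 2000L, thin = 1L),
                paper = list(n_chains = 3L, n_burnin = 10000L, n_keep = 10000L, thin = 25L))
  out <- list(n_chains = n_chains %||% def$n_chains,
              n_burnin = n_burnin %||% def$n_burnin,
              n_keep = n_keep %||% def$n_keep,
              thin = thin %||% def$thin,
              seed = as.integer(seed), preset = preset)
  with(out, stopifnot(n_chains >= 1, n_burnin >= 0, n_keep >= 2, thin >= 1))
  structure(out, class = "stm_mcmc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parameter-column layout; must match the packing order in src/sampler.cpp
layout_par_names <- function(W, useq, m1, shared) {
  nm <- c(sprintf("alpha_at[%d]", 1:W), sprintf("beta_at[%d]", 1:W),
          "t0_at", "rho_at", "sigma_at")
  if (useq) nm <- c(nm, sprintf("alpha_q[%d]", 1:W), sprintf("beta_q[%d]", 1:W),
                    "t0_q", "rho_q", "sigma_q")
  nm <- c(nm, sprintf("max_wt[%d]", 1:W), sprintf("min_wt[%d]", 1:W), "t0_wt")
  nm <- c(nm, "theta0", "theta1", if (useq) "theta2",
          if (!shared) "theta0p", "theta1p", if (useq) "theta2p",
          "sigma_max", "sigma_min")
  if (m1) c(nm, "rho_wt", "sigma_wt")
  else c(nm, "delta", if (useq) "gamma", "sigma_zeta")
}

#' Fit the decomposition/link model by MCMC
#'
#' Draws from the joint posterior of all model parameters and of the latent
#' values at unobserved days (gap filling, hindcast and forecast days included:
#' any day where WT is missing but the covariates are available receives
#' posterior-predictive WT draws as part of the fit). The sampler combines
#' exact conjugate Gibbs updates for all conditionally Gaussian parameters with
#' adaptive random-walk Metropolis for the phases, autocorrelations and scale
#' parameters; chains are initialized from a least-squares decomposition with
#' chain-specific jitter.
#'
#' @param data an `stm_data` object.
#' @param config an [stm_config()]; its `use_discharge = NA` resolves to the
#'   data's discharge availability.
#' @param priors an `stm_priors` object, default [default_priors()].
#' @param mcmc an [stm_mcmc()] settings object.
#' @return object of class `stm_fit` with elements
#'   \describe{
#'     \item{draws}{a [coda::mcmc.list] of parameter draws.}
#'     \item{latent}{matrices of latent draws at missing days per series
#'       (`wt`, `at`, `q`), each total-kept-draws x n-missing, plus the day
#'       indices they refer to.}
#'     \item{convergence}{data.frame with split R-hat and effective sample size
#'       per parameter, and a pass flag (R-hat <= 1.1 and ESS >= 100).}
#'     \item{data, config, priors, mcmc}{the inputs.}
#'   }
#' @export
stm_fit <- function(data, config = stm_config(), priors = NULL, mcmc = stm_mcmc()) {
  stopifnot(inherits(data, "stm_data"), inherits(config, "stm_config"),
            inherits(mcmc, "stm_mcmc"))
  if (is.na(config$use_discharge)) config$use_discharge <- data$use_discharge
  if (config$use_discharge && !data$use_discharge) {
    stop("config requests discharge but the dataset has no discharge series")
  }
  check_overlap(data, config$use_discharge)
  if (is.null(priors)) priors <- default_priors(data, config)
  validate_priors(priors, data)

  W <- n_windows(data$windows)
  d <- data$windows$day
  cdata <- list(
    T = length(data$dates), W = W, win = d$win,
    winlo = tapply(seq_along(d$win), d$win, min)[as.character(1:W)],
    winhi = tapply(seq_along(d$win), d$win, max)[as.character(1:W)],
    doy = as.numeric(d$doy), nyr = as.numeric(d$n_year),
    wt = data$wt, at = data$at, q = data$q %||% numeric(0),
    obs_wt = as.integer(!is.na(data$wt)), obs_at = as.integer(!is.na(data$at)),
    obs_q = if (data$use_discharge) as.integer(!is.na(data$q)) else integer(0)
  )
  cdata$winlo <- as.integer(cdata$winlo); cdata$winhi <- as.integer(cdata$winhi)
  cconfig <- list(use_discharge = config$use_discharge, m1 = config$variant == "m1",
                  shared_intercept = config$shared_intercept)
  cpriors <- flatten_priors(priors, config$use_discharge)

  base_init <- ls_init(data, config)
  nm <- layout_par_names(W, config$use_discharge, cconfig$m1, config$shared_intercept)

  chains <- vector("list", mcmc$n_chains)
  lat <- list(wt = list(), at = list(), q = list())
  raw <- NULL
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed * 1000L + ch)
    st <- jitter_init(base_init, config)
    if (config$shared_intercept) st$theta0p <- st$theta0
    cd <- cdata
    cd$wt[!is.finite(cd$wt)] <- st$fill_wt[!is.finite(cd$wt)]
    cd$at[!is.finite(cd$at)] <- st$fill_at[!is.finite(cd$at)]
    if (config$use_discharge) cd$q[!is.finite(cd$q)] <- st$fill_q[!is.finite(cd$q)]
    lp0 <- joint_logposterior(data, state_to_params(st, config), priors, config,
                              latent = list(wt = cd$wt[cdata$obs_wt == 0L],
                                            at = cd$at[cdata$obs_at == 0L],
                                            q = if (config$use_discharge) cd$q[cdata$obs_q == 0L]))
    if (!is.finite(lp0)) stop("non-finite log-posterior at initialization (chain ", ch, ")")
    raw <- .stm_run_chain(cd, st, cpriors, cconfig,
                          as.integer(mcmc$n_burnin), as.integer(mcmc$n_keep),
                          as.integer(mcmc$thin))
    dr <- raw$draws
    colnames(dr) <- nm
    chains[[ch]] <- coda::mcmc(dr, start = mcmc$n_burnin + 1L, thin = mcmc$thin)
    lat$wt[[ch]] <- raw$lat_wt; lat$at[[ch]] <- raw$lat_at; lat$q[[ch]] <- raw$lat_q
  }
  draws <- coda::mcmc.list(chains)
  latent <- list(
    wt = do.call(rbind, lat$wt), at = do.call(rbind, lat$at),
    q = if (config$use_discharge) do.call(rbind, lat$q),
    idx_wt = raw$mis_wt + 1L, idx_at = raw$mis_at + 1L,
    idx_q = if (config$use_discharge) raw$mis_q + 1L
  )
  fit <- structure(list(draws = draws, latent = latent,
                        data = data, config = config, priors = priors, mcmc = mcmc),
                   class = "stm_fit")
  fit$convergence <- convergence_report(draws)
  fit
}

check_overlap <- function(data, useq = data$use_discharge) {
  d <- data$windows$day
  cov_ok <- !is.na(data$at)
  if (useq) cov_ok <- cov_ok & !is.na(data$q)
  full_w <- data$windows$window$win[data$windows$window$full]
  n_over <- sum(vapply(full_w, function(w) {
    i <- d$win == w
    any(!is.na(data$wt[i])) && mean(cov_ok[i]) > 0.5
  }, logical(1)))
  if (n_over < 2) {
    stop("water temperature must overlap the covariates on at least 2 full windows")
  }
  invisible(TRUE)
}

flatten_priors <- function(pr, useq) {
  out <- list(
    theta_mean = pr$theta$mean, theta_sd = pr$theta$sd,
    dg_mean = pr$deltagamma$mean, dg_sd = pr$deltagamma$sd,
    rho_lo = pr$rho$lo, rho_hi = pr$rho$hi,
    t0_lo = pr$t0$lo, t0_hi = pr$t0$hi,
    alpha_at_mean = pr$alpha_at$mean, alpha_at_sd = pr$alpha_at$sd,
    beta_at_sd = pr$beta_at$sd,
    sigma_at_sd = pr$sigma_at$sd, sigma_zeta_sd = pr$sigma_zeta$sd,
    sigma_max_sd = pr$sigma_max$sd, sigma_min_sd = pr$sigma_min$sd,
    sigma_wt_sd = pr$sigma_wt$sd
  )
  if (useq) {
    out$alpha_q_mean <- pr$alpha_q$mean; out$alpha_q_sd <- pr$alpha_q$sd
    out$beta_q_sd <- pr$beta_q$sd; out$sigma_q_sd <- pr$sigma_q$sd
  }
  out
}

# least-squares starting state; window-mean vectors expanded to length W
ls_init <- function(data, config) {
  W <- n_windows(data$windows)
  at <- ls_decompose(data$at, data$windows)
  wt <- ls_decompose(data$wt, data$windows)
  st <- list(
    alpha_at = at$alpha, beta_at = pmax(at$beta, 0.01), t0_at = at$t0,
    rho_at = ar1_moment_init(at$resid), sigma_at = at$resid_sd,
    max_wt = wt$alpha + wt$beta, min_wt = wt$alpha - wt$beta, t0_wt = wt$t0,
    sigma_max = 1, sigma_min = 1
  )
  mx_at <- at$alpha + at$beta; mn_at <- at$alpha - at$beta
  if (config$use_discharge) {
    q <- ls_decompose(data$q, data$windows)
    st$alpha_q <- q$alpha; st$beta_q <- pmax(q$beta, 0.01); st$t0_q <- q$t0
    st$rho_q <- ar1_moment_init(q$resid); st$sigma_q <- q$resid_sd
    mn_q <- q$alpha - q$beta; mx_q <- q$alpha + q$beta
  }
  cf_max <- if (config$use_discharge) safe_lm(st$max_wt, cbind(mx_at, mn_q))
            else safe_lm(st$max_wt, cbind(mx_at))
  cf_min <- if (config$use_discharge) safe_lm(st$min_wt, cbind(mn_at, mx_q))
            else safe_lm(st$min_wt, cbind(mn_at))
  st$theta0 <- cf_max[1]; st$theta1 <- cf_max[2]
  st$theta2 <- if (config$use_discharge) cf_max[3] else 0
  st$theta0p <- cf_min[1]; st$theta1p <- cf_min[2]
  st$theta2p <- if (config$use_discharge) cf_min[3] else 0
  if (config$variant == "m1") {
    st$rho_wt <- ar1_moment_init(wt$resid); st$sigma_wt <- wt$resid_sd
  } else {
    cf <- safe_lm(wt$resid, cbind(at$resid), intercept = FALSE)
    st$delta <- cf[1]; st$gamma <- 0; st$sigma_zeta <- wt$resid_sd
  }
  # fill values for latent initialization: seasonal LS surface
  d <- data$windows$day
  st$fill_at <- at$alpha[d$win] + at$beta[d$win] * sin(2 * pi / d$n_year * (d$doy - at$t0))
  st$fill_wt <- wt$alpha[d$win] + wt$beta[d$win] * sin(2 * pi / d$n_year * (d$doy - wt$t0))
  if (config$use_discharge) {
    q <- ls_decompose(data$q, data$windows)
    st$fill_q <- q$alpha[d$win] + q$beta[d$win] * sin(2 * pi / d$n_year * (d$doy - q$t0))
  }
  st
}

ar1_moment_init <- function(resid) {
  r <- resid[!is.na(resid)]
  if (length(r) < 10) return(0.3)
  rho <- acf(r, lag.max = 1, plot = FALSE)$acf[2]
  max(min(rho, 0.97), -0.97)
}

safe_lm <- function(y, X, intercept = TRUE) {
  ok <- complete.cases(y, X)
  if (sum(ok) <= ncol(X) + intercept) {
    return(c(if (intercept) mean(y, na.rm = TRUE) else NULL, rep(0, ncol(X))))
  }
  cf <- if (intercept) coef(lm(y[ok] ~ X[ok, , drop = FALSE]))
        else coef(lm(y[ok] ~ X[ok, , drop = FALSE] - 1))
  cf[!is.finite(cf)] <- 0
  cf
}

# chain-specific overdispersion around the least-squares start
jitter_init <- function(st, config) {
  j <- function(x, s) x + rnorm(length(x), 0, s)
  st$alpha_at <- j(st$alpha_at, 0.5); st$beta_at <- pmax(j(st$beta_at, 0.3), 0.01)
  st$t0_at <- (st$t0_at + rnorm(1, 0, 3)) %% 365
  st$rho_at <- min(max(j(st$rho_at, 0.05), -0.95), 0.95)
  st$sigma_at <- st$sigma_at * exp(rnorm(1, 0, 0.1))
  st$max_wt <- j(st$max_wt, 0.5); st$min_wt <- pmin(j(st$min_wt, 0.5), st$max_wt - 0.1)
  st$t0_wt <- (st$t0_wt + rnorm(1, 0, 3)) %% 365
  for (p in c("theta0", "theta1", "theta2", "theta0p", "theta1p", "theta2p")) {
    st[[p]] <- j(st[[p]], 0.1)
  }
  if (!config$use_discharge) { st$theta2 <- 0; st$theta2p <- 0 }
  st$sigma_max <- st$sigma_max * exp(rnorm(1, 0, 0.2))
  st$sigma_min <- st$sigma_min * exp(rnorm(1, 0, 0.2))
  if (config$use_discharge) {
    st$alpha_q <- j(st$alpha_q, 0.2); st$beta_q <- pmax(j(st$beta_q, 0.1), 0.01)
    st$t0_q <- (st$t0_q + rnorm(1, 0, 3)) %% 365
    st$rho_q <- min(max(j(st$rho_q, 0.05), -0.95), 0.95)
    st$sigma_q <- st$sigma_q * exp(rnorm(1, 0, 0.1))
  }
  if (config$variant == "m1") {
    st$rho_wt <- min(max(j(st$rho_wt, 0.05), -0.95), 0.95)
    st$sigma_wt <- st$sigma_wt * exp(rnorm(1, 0, 0.1))
  } else {
    st$delta <- j(st$delta, 0.1); st$gamma <- j(st$gamma, 0.1)
    if (!config$use_discharge) st$gamma <- 0
    st$sigma_zeta <- st$sigma_zeta * exp(rnorm(1, 0, 0.1))
  }
  st
}

state_to_params <- function(st, config) {
  p <- list(
    at = list(alpha = st$alpha_at, beta = st$beta_at, t0 = st$t0_at,
              rho = st$rho_at, sigma = st$sigma_at),
    q = if (config$use_discharge)
      list(alpha = st$alpha_q, beta = st$beta_q, t0 = st$t0_q,
           rho = st$rho_q, sigma = st$sigma_q),
    link = link_params(st$theta0, st$theta1, st$theta2, st$theta0p, st$theta1p,
                       st$theta2p, st$sigma_max, st$sigma_min)
  )
  p$wt <- if (config$variant == "m1") {
    list(max = st$max_wt, min = st$min_wt, t0 = st$t0_wt,
         rho = st$rho_wt, sigma = st$sigma_wt)
  } else {
    list(max = st$max_wt, min = st$min_wt, t0 = st$t0_wt,
         delta = st$delta, gamma = st$gamma, sigma_zeta = st$sigma_zeta)
  }
  p
}

#' Convergence diagnostics for a set of chains
#'
#' Computes the split R-hat (each chain halved, between/within variance ratio)
#' and the effective sample size for every monitored parameter. A parameter
#' passes when split R-hat <= 1.1 and ESS >= 100.
#'
#' @param draws a [coda::mcmc.list].
#' @return data.frame with columns `parameter`, `rhat`, `ess`, `pass`.
#' @export
convergence_report <- function(draws) {
  mat <- lapply(draws, as.matrix)
  pars <- colnames(mat[[1]])
  rhat <- vapply(pars, function(p) {
    split_rhat(lapply(mat, function(m) m[, p]))
  }, numeric(1))
  ess <- tryCatch(as.numeric(coda::effectiveSize(draws))[seq_along(pars)],
                  error = function(e) rep(NA_real_, length(pars)))
  data.frame(parameter = pars, rhat = rhat, ess = ess,
             pass = is.finite(rhat) & rhat <= 1.1 & ess >= 100,
             row.names = NULL)
}

split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- floor(length(x) / 2)
    list(x[1:n], x[(n + 1):(2 * n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  Wv <- mean(vars); Bv <- n * stats::var(means)
  if (Wv <= 0) return(1)
  sqrt(((n - 1) / n * Wv + Bv / n) / Wv)
}

#' @export
print.stm_fit <- function(x, ...) {
  cat(sprintf("stm_fit: variant %s, discharge %s, %d chains x %d kept (thin %d)\n",
              toupper(x$config$variant), if (x$config$use_discharge) "yes" else "no",
              x$mcmc$n_chains, x$mcmc$n_keep, x$mcmc$thin))
  cv <- x$convergence
  cat(sprintf("  convergence: %d/%d parameters pass (max split R-hat %.3f)\n",
              sum(cv$pass), nrow(cv), max(cv$rhat, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.stm_fit <- function(object, ...) {
  m <- as.matrix(object$draws)
  q <- t(apply(m, 2, quantile, c(0.025, 0.25, 0.5, 0.75, 0.975)))
  out <- data.frame(parameter = colnames(m), mean = colMeans(m), q,
                    check.names = FALSE, row.names = NULL)
  names(out)[3:7] <- c("q2.5", "q25", "q50", "q75", "q97.5")
  merge(out, object$convergence, by = "parameter", sort = FALSE)
}

# stacked draws matrix (all chains) and matching latent matrices
stacked_draws <- function(fit) as.matrix(fit$draws)
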