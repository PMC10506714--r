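#' Joint log-posterior of the full hierarchical model
#'
#' Reference implementation of the model's joint density, assembled term by
#' term from the package's building blocks: the seasonal decomposition of each
#' series with AR1 covariate residuals, the window-extrema regressions linking
#' WT to the covariates, the daily residual link (M2) or AR1 WT residuals (M1),
#' and the priors. Missing observations contribute no likelihood term unless
#' latent values are supplied for them, in which case they enter as latent
#' draws. Parameter values violating the model invariants (nonstationary rho,
#' nonpositive scales, negative covariate amplitudes, phase out of range)
#' return `-Inf` rather than raising an error, so a sampler can treat them as
#' rejected states.
#'
#' This function exists as the single written-out statement of the posterior
#' targeted by [stm_fit()]; the compiled sampler is validated against it.
#'
#' @param data an `stm_data` object.
#' @param params parameter list: `at` and (optionally) `q` each with
#'   `alpha`, `beta`, `t0`, `rho`, `sigma`; `wt` with `max`, `min`, `t0` plus
#'   either `delta`, `gamma`, `sigma_zeta` (M2) or `rho`, `sigma` (M1); and
#'   `link` (see [link_params()]).
#' @param priors an `stm_priors` object (see [default_priors()]).
#' @param config an [stm_config()].
#' @param latent optional list with numeric vectors `wt`, `at`, `q` giving
#'   values at that series' missing days (in day order). Covariate gaps and,
#'   under M1, WT gaps interrupt the AR1 chain, so their latent values are
#'   required when such gaps exist; latent WT under M2 is optional (the days
#'   are likelihood leaves).
#' @return the joint log-posterior (a finite scalar, or `-Inf` for invalid
#'   parameter values).
#' @export
joint_logposterior <- function(data, params, priors, config = stm_config(),
                               latent = NULL) {
  stopifnot(inherits(data, "stm_data"))
  if (is.na(config$use_discharge)) config$use_discharge <- data$use_discharge
  useq <- config$use_discharge
  m1 <- config$variant == "m1"
  W <- n_windows(data$windows)
  d <- data$windows$day
  pa <- params$at; pq <- params$q; pw <- params$wt; th <- params$link

  # ---- invariant screening (rejected state, not an error) -----------------
  bad <- function() -Inf
  if (abs(pa$rho) >= 1 || pa$sigma <= 0) return(bad())
  if (any(pa$beta < 0)) return(bad())
  if (pa$t0 < priors$t0$lo || pa$t0 >= priors$t0$hi) return(bad())
  if (useq) {
    if (is.null(pq)) stop("config uses discharge but params$q is missing")
    if (abs(pq$rho) >= 1 || pq$sigma <= 0 || any(pq$beta < 0)) return(bad())
    if (pq$t0 < priors$t0$lo || pq$t0 >= priors$t0$hi) return(bad())
  }
  if (th$sigma_max <= 0 || th$sigma_min <= 0) return(bad())
  if (!useq && (th$theta2 != 0 || th$theta2p != 0)) {
    stop("theta2 and theta2p must be identically 0 without discharge")
  }
  if (config$shared_intercept && th$theta0p != th$theta0) {
    stop("shared_intercept requires theta0p == theta0")
  }
  if (pw$t0 < priors$t0$lo || pw$t0 >= priors$t0$hi) return(bad())
  if (m1) {
    if (abs(pw$rho) >= 1 || pw$sigma <= 0) return(bad())
  } else {
    if (pw$sigma_zeta <= 0) return(bad())
    if (!useq && pw$gamma != 0) stop("gamma must be identically 0 without discharge")
  }

  # ---- assemble series values with latent fill ----------------------------
  fill <- function(values, lat, label) {
    mis <- which(is.na(values))
    if (length(mis) == 0L) return(list(v = values, complete = TRUE))
    if (is.null(lat)) return(list(v = values, complete = FALSE))
    if (length(lat) != length(mis)) {
      stop("latent `", label, "` must have length ", length(mis))
    }
    values[mis] <- lat
    list(v = values, complete = TRUE)
  }
  at <- fill(data$at, latent$at, "at")
  if (!at$complete) stop("latent values required for the air-temperature gaps")
  qv <- NULL
  if (useq) {
    qv <- fill(data$q, latent$q, "q")
    if (!qv$complete) stop("latent values required for the discharge gaps")
  }
  wt <- fill(data$wt, latent$wt, "wt")
  if (m1 && !wt$complete && anyNA(data$wt)) {
    stop("latent values required for the WT gaps under model M1")
  }

  omega <- 2 * pi / d$n_year
  lp <- 0

  # ---- module 1: covariate decomposition with AR1 residuals ---------------
  cov_ll <- function(values, p) {
    s <- p$alpha[d$win] + p$beta[d$win] * sin(omega * (d$doy - p$t0))
    ar1_logdensity(values - s, p$rho, p$sigma)
  }
  lp <- lp + cov_ll(at$v, pa)
  if (useq) lp <- lp + cov_ll(qv$v, pq)

  # ---- module 2a: window extrema regression -------------------------------
  max_at <- pa$alpha + pa$beta; min_at <- pa$alpha - pa$beta
  mu <- wt_extrema_mean(th, max_at, min_at,
                        min_q = if (useq) pq$alpha - pq$beta,
                        max_q = if (useq) pq$alpha + pq$beta)
  lp <- lp + sum(dnorm(pw$max, mu$mu_max, th$sigma_max, log = TRUE)) +
             sum(dnorm(pw$min, mu$mu_min, th$sigma_min, log = TRUE))

  # ---- daily WT: module 2b link (M2) or AR1 residuals (M1) ----------------
  alpha_wt <- (pw$max + pw$min) / 2; beta_wt <- (pw$max - pw$min) / 2
  s_wt <- alpha_wt[d$win] + beta_wt[d$win] * sin(omega * (d$doy - pw$t0))
  if (m1) {
    lp <- lp + ar1_logdensity(wt$v - s_wt, pw$rho, pw$sigma)
  } else {
    eps_at <- at$v - (pa$alpha[d$win] + pa$beta[d$win] * sin(omega * (d$doy - pa$t0)))
    eps_q <- if (useq) {
      qv$v - (pq$alpha[d$win] + pq$beta[d$win] * sin(omega * (d$doy - pq$t0)))
    }
    link <- list(delta = pw$delta, gamma = if (useq) pw$gamma else 0,
                 sigma_zeta = pw$sigma_zeta)
    mu_d <- s_wt + short_term_link(link, eps_at, eps_q, d$doy, pw$t0, d$n_year)
    use <- if (wt$complete) rep(TRUE, length(mu_d)) else !is.na(data$wt)
    lp <- lp + sum(dnorm(wt$v[use], mu_d[use], pw$sigma_zeta, log = TRUE))
  }

  # ---- priors -------------------------------------------------------------
  half_norm <- function(x, sd) dnorm(x, 0, sd, log = TRUE) + log(2)
  amean_at <- rep_len(priors$alpha_at$mean, W)
  lp <- lp + sum(dnorm(pa$alpha, amean_at, priors$alpha_at$sd, log = TRUE)) +
             sum(half_norm(pa$beta, priors$beta_at$sd)) +
             half_norm(pa$sigma, priors$sigma_at$sd) -
             log(priors$t0$hi - priors$t0$lo) -
             log(priors$rho$hi - priors$rho$lo)
  if (abs(pa$rho) >= 1 || pa$rho < priors$rho$lo || pa$rho > priors$rho$hi) return(bad())
  if (useq) {
    amean_q <- rep_len(priors$alpha_q$mean, W)
    lp <- lp + sum(dnorm(pq$alpha, amean_q, priors$alpha_q$sd, log = TRUE)) +
               sum(half_norm(pq$beta, priors$beta_q$sd)) +
               half_norm(pq$sigma, priors$sigma_q$sd) -
               log(priors$t0$hi - priors$t0$lo) -
               log(priors$rho$hi - priors$rho$lo)
    if (pq$rho < priors$rho$lo || pq$rho > priors$rho$hi) return(bad())
  }
  th_free <- c(th$theta0, th$theta1, if (useq) th$theta2,
               if (!config$shared_intercept) th$theta0p, th$theta1p,
               if (useq) th$theta2p)
  lp <- lp + sum(dnorm(th_free, priors$theta$mean, priors$theta$sd, log = TRUE)) +
             half_norm(th$sigma_max, priors$sigma_max$sd) +
             half_norm(th$sigma_min, priors$sigma_min$sd) -
             log(priors$t0$hi - priors$t0$lo)
  if (m1) {
    if (pw$rho < priors$rho$lo || pw$rho > priors$rho$hi) return(bad())
    lp <- lp + half_norm(pw$sigma, priors$sigma_wt$sd) -
               log(priors$rho$hi - priors$rho$lo)
  } else {
    dg <- c(pw$delta, if (useq) pw$gamma)
    lp <- lp + sum(dnorm(dg, priors$deltagamma$mean, priors$deltagamma$sd, log = TRUE)) +
               half_norm(pw$sigma_zeta, priors$sigma_zeta$sd)
  }
  lp
}
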