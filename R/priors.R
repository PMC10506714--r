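#' Default weakly-informative priors scaled to the data
#'
#' Builds the prior specification used by [stm_fit()]. Defaults are weakly
#' informative relative to daily temperature data: Normal(0, 10) on the
#' regression coefficients and the daily link gains, Uniform(-1, 1) on the AR1
#' autocorrelations, Uniform(0, 365) on the phases, Normal(per-window empirical
#' mean, 10) on the covariate window means, half-Normal(10) on the covariate
#' amplitudes, and half-Normal with scale twice the empirical residual standard
#' deviation (from a least-squares sinusoid fit) on every scale parameter.
#' Any entry can be overridden, subject to the model's invariants.
#'
#' @param data an `stm_data` object.
#' @param config model configuration from [stm_config()].
#' @param overrides named list merged over the defaults; names and fields must
#'   match the returned structure (e.g. `list(rho = list(lo = -0.5, hi = 0.99))`).
#' @return a list of class `stm_priors` with entries `theta`, `deltagamma`
#'   (`mean`, `sd`), `rho`, `t0` (`lo`, `hi`), `alpha_at`, `alpha_q` (`mean`
#'   possibly per window, `sd`), `beta_at`, `beta_q`, `sigma_at`, `sigma_q`,
#'   `sigma_zeta`, `sigma_max`, `sigma_min`, `sigma_wt` (half-Normal `sd`).
#' @export
default_priors <- function(data, config = stm_config(), overrides = list()) {
  stopifnot(inherits(data, "stm_data"))
  ls_at <- ls_decompose(data$at, data$windows)
  ls_wt <- ls_decompose(data$wt, data$windows)
  window_mean <- function(v) {
    mu <- tapply(v, data$windows$day$win, mean, na.rm = TRUE)
    mu <- as.numeric(mu)
    mu[!is.finite(mu)] <- mean(v, na.rm = TRUE)
    mu
  }
  pr <- list(
    theta = list(mean = 0, sd = 10),
    deltagamma = list(mean = 0, sd = 10),
    rho = list(lo = -1, hi = 1),
    t0 = list(lo = 0, hi = 365),
    alpha_at = list(mean = window_mean(data$at), sd = 10),
    beta_at = list(sd = 10),
    sigma_at = list(sd = 2 * ls_at$resid_sd),
    sigma_zeta = list(sd = 2 * ls_wt$resid_sd),
    sigma_wt = list(sd = 2 * ls_wt$resid_sd),
    sigma_max = list(sd = extrema_resid_scale(ls_wt, ls_at)),
    sigma_min = list(sd = extrema_resid_scale(ls_wt, ls_at))
  )
  if (data$use_discharge) {
    ls_q <- ls_decompose(data$q, data$windows)
    pr$alpha_q <- list(mean = window_mean(data$q), sd = 10)
    pr$beta_q <- list(sd = 10)
    pr$sigma_q <- list(sd = 2 * ls_q$resid_sd)
  }
  pr <- merge_priors(pr, overrides)
  validate_priors(pr, data)
  structure(pr, class = "stm_priors")
}

merge_priors <- function(pr, overrides) {
  for (nm in names(overrides)) {
    if (!nm %in% names(pr)) stop("unknown prior entry: ", nm)
    for (f in names(overrides[[nm]])) {
      if (!f %in% names(pr[[nm]])) stop("unknown field `", f, "` in prior `", nm, "`")
      pr[[nm]][[f]] <- overrides[[nm]][[f]]
    }
  }
  pr
}

validate_priors <- function(pr, data) {
  for (nm in grep("^sigma", names(pr), value = TRUE)) {
    if (!is.finite(pr[[nm]]$sd) || pr[[nm]]$sd <= 0) {
      stop("prior `", nm, "`: half-Normal scale must be positive (sigma > 0)")
    }
  }
  for (nm in c("theta", "deltagamma", "alpha_at", if (data$use_discharge) "alpha_q")) {
    if (any(!is.finite(pr[[nm]]$mean)) || pr[[nm]]$sd <= 0) {
      stop("prior `", nm, "`: Normal prior needs finite mean and positive sd")
    }
  }
  for (nm in c("beta_at", if (data$use_discharge) "beta_q")) {
    if (pr[[nm]]$sd <= 0) stop("prior `", nm, "`: half-Normal scale must be positive")
  }
  if (pr$rho$lo < -1 || pr$rho$hi > 1 || pr$rho$lo >= pr$rho$hi) {
    stop("prior `rho`: bounds must satisfy -1 <= lo < hi <= 1")
  }
  if (pr$t0$lo < 0 || pr$t0$hi > 365 || pr$t0$lo >= pr$t0$hi) {
    stop("prior `t0`: bounds must satisfy 0 <= lo < hi <= 365")
  }
  invisible(pr)
}

# scale for the half-Normal prior on the extrema-regression residual SDs:
# twice the spread left in the WT window extrema after projecting on AT's,
# with a floor for very short series
extrema_resid_scale <- function(ls_wt, ls_at) {
  mx_wt <- ls_wt$alpha + ls_wt$beta
  mx_at <- ls_at$alpha + ls_at$beta
  ok <- is.finite(mx_wt) & is.finite(mx_at)
  if (sum(ok) >= 4) {
    r <- stats::residuals(lm(mx_wt[ok] ~ mx_at[ok]))
    max(2 * sd(r), 0.5)
  } else {
    5
  }
}

# Least-squares seasonal decomposition of one (gappy) daily series: common
# phase from a sin/cos regression, then per-window mean and amplitude.
# Used for prior scaling and chain initialization only.
ls_decompose <- function(values, windows) {
  d <- windows$day
  ok <- !is.na(values)
  x <- 2 * pi / d$n_year * d$doy
  fit <- lm(values[ok] ~ sin(x[ok]) + cos(x[ok]))
  b <- coef(fit)[2]; cc <- coef(fit)[3]
  # b*sin(x) + c*cos(x) = A*sin(x - w*t0) with w*t0 = -atan2(c, b)
  t0 <- ((-atan2(cc, b)) * 365 / (2 * pi)) %% 365
  W <- n_windows(windows)
  alpha <- numeric(W); beta <- numeric(W)
  s <- sin(2 * pi / d$n_year * (d$doy - t0))
  for (w in seq_len(W)) {
    i <- which(d$win == w & ok)
    if (length(i) >= 5) {
      cf <- coef(lm(values[i] ~ s[i]))
      alpha[w] <- cf[1]; beta[w] <- max(cf[2], 0.01)
    } else {
      alpha[w] <- NA_real_; beta[w] <- NA_real_
    }
  }
  # fill sparse windows from the overall fit
  if (anyNA(alpha)) {
    a0 <- mean(values, na.rm = TRUE); b0 <- max(sqrt(b^2 + cc^2), 0.01)
    alpha[is.na(alpha)] <- a0; beta[is.na(beta)] <- b0
  }
  resid <- values - (alpha[d$win] + beta[d$win] * s)
  list(alpha = alpha, beta = beta, t0 = t0,
       resid_sd = max(sd(resid, na.rm = TRUE), 1e-3), resid = resid)
}
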