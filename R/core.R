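#' Seasonal decomposition parameters for one series
#'
#' The deterministic part of the decomposition of a daily series is
#' `alpha[y] + beta[y] * sin(2*pi/n * (t - t0))`, where `y` indexes six-month
#' windows, `t` is day of year (1-based), `n` is the number of days in that
#' calendar year (365 or 366) and `t0` is the phase in days. The amplitude is
#' constrained nonnegative and the phase to `[0, 365)`, which resolves the sign
#' and phase unidentifiability of `alpha + beta * sin`.
#'
#' @param alpha per-window means (series units).
#' @param beta per-window amplitudes, `>= 0`.
#' @param t0 phase offset in days, in `[0, 365)`.
#' @return object of class `stm_seasonal`.
#' @export
seasonal_params <- function(alpha, beta, t0) {
  if (length(alpha) != length(beta)) stop("`alpha` and `beta` lengths differ")
  if (any(!is.finite(alpha)) || any(!is.finite(beta))) stop("non-finite seasonal parameter")
  if (any(beta < 0)) stop("`beta` must be nonnegative in every window")
  if (!is.finite(t0) || t0 < 0 || t0 >= 366) stop("`t0` must lie in [0, 366)")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta), t0 = as.numeric(t0)),
            class = "stm_seasonal")
}

#' Reparametrize a seasonal signal by its window extrema
#'
#' The seasonal extrema of window `y` are `max_y = alpha_y + beta_y` and
#' `min_y = alpha_y - beta_y`; these are the quantities linked across series by
#' the window-level regression. The conversion is exact algebra, and
#' `from_extrema(to_extrema(sp), sp$t0)` reproduces `alpha` and `beta`
#' bit-for-bit.
#'
#' @param sp an `stm_seasonal` object.
#' @return `to_extrema`: list with components `max` and `min` (class
#'   `stm_extrema`); `from_extrema`: an `stm_seasonal`.
#' @export
to_extrema <- function(sp) {
  stopifnot(inherits(sp, "stm_seasonal"))
  structure(list(max = sp$alpha + sp$beta, min = sp$alpha - sp$beta),
            class = "stm_extrema")
}

#' @rdname to_extrema
#' @param ep an `stm_extrema` object (per-window `max` and `min`, `max >= min`).
#' @param t0 phase offset in days for the reconstructed signal.
#' @export
from_extrema <- function(ep, t0) {
  stopifnot(inherits(ep, "stm_extrema"))
  if (any(ep$max < ep$min)) stop("extrema with max < min")
  seasonal_params((ep$max + ep$min) / 2, (ep$max - ep$min) / 2, t0)
}

#' Evaluate the seasonal signal at given days
#'
#' Returns `alpha[y(t)] + beta[y(t)] * sin(2*pi/n * (doy - t0))` for each
#' requested day index, with `doy` the day of year and `n` the length of that
#' calendar year.
#'
#' @param sp an `stm_seasonal` with one `alpha`/`beta` pair per window of
#'   `windows`.
#' @param windows an `stm_windows` index (see [build_windows()]).
#' @param t integer day indices into `windows$day` (defaults to all days).
#' @return numeric vector of signal values.
#' @export
seasonal_signal <- function(sp, windows, t = seq_len(nrow(windows$day))) {
  stopifnot(inherits(sp, "stm_seasonal"), inherits(windows, "stm_windows"))
  if (length(sp$alpha) != n_windows(windows)) {
    stop("seasonal parameters cover ", length(sp$alpha), " windows but the index has ",
         n_windows(windows))
  }
  t <- as.integer(t)
  if (any(t < 1L | t > nrow(windows$day))) stop("day index outside the window range")
  d <- windows$day[t, ]
  sp$alpha[d$win] + sp$beta[d$win] * sin(2 * pi / d$n_year * (d$doy - sp$t0))
}

#' Zero-mean stationary AR1 log-density and simulation
#'
#' The short-term residuals of the covariate series (and of WT under model M1)
#' follow a first-order autoregressive process centred on zero: the first value
#' is drawn from the stationary law `N(0, sigma^2 / (1 - rho^2))` and each
#' subsequent value from `N(rho * eps[t-1], sigma^2)`.
#'
#' @param eps numeric residual vector.
#' @param rho autocorrelation, `|rho| < 1`.
#' @param sigma innovation standard deviation, `> 0`.
#' @return `ar1_logdensity`: the joint log-density of `eps`;
#'   `ar1_simulate`: a simulated residual vector.
#' @export
ar1_logdensity <- function(eps, rho, sigma) {
  check_ar1(rho, sigma)
  if (length(eps) == 0L) return(0)
  n <- length(eps)
  ll <- dnorm(eps[1L], 0, sigma / sqrt(1 - rho^2), log = TRUE)
  if (n > 1L) {
    ll <- ll + sum(dnorm(eps[-1L], rho * eps[-n], sigma, log = TRUE))
  }
  ll
}

#' @rdname ar1_logdensity
#' @param n length of the simulated vector.
#' @param seed optional integer; when supplied the draw is reproducible
#'   (`set.seed` is called locally without disturbing the caller's RNG stream).
#' @export
ar1_simulate <- function(n, rho, sigma, seed = NULL) {
  check_ar1(rho, sigma)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  eps <- numeric(n)
  if (n == 0L) return(eps)
  eps[1L] <- rnorm(1, 0, sigma / sqrt(1 - rho^2))
  if (n > 1L) for (t in 2:n) eps[t] <- rho * eps[t - 1L] + rnorm(1, 0, sigma)
  eps
}

check_ar1 <- function(rho, sigma) {
  if (!is.finite(rho) || abs(rho) >= 1) stop("AR1 requires |rho| < 1 (stationarity)")
  if (!is.finite(sigma) || sigma <= 0) stop("AR1 requires sigma > 0")
  invisible(TRUE)
}

#' Window-extrema regression means
#'
#' The WT seasonal extrema of window `y` are normally distributed around means
#' that are linear in the covariate extrema:
#' `mu_max = theta0 + theta1 * max_AT + theta2 * min_Q` and
#' `mu_min = theta0p + theta1p * min_AT + theta2p * max_Q`.
#' Warm air maxima drive warm water maxima; pairing the WT maximum with the
#' *minimum* log-discharge (and vice versa) encodes the cooling effect of high
#' flow in summer and its warming effect in winter. Without discharge the Q
#' slopes are identically zero.
#'
#' @param theta list with `theta0, theta1, theta2, theta0p, theta1p, theta2p,
#'   sigma_max, sigma_min` (see [link_params()]).
#' @param max_at,min_at per-window AT seasonal extrema (degC).
#' @param min_q,max_q per-window log-discharge seasonal extrema, or `NULL`
#'   when the model runs without discharge.
#' @return list with `mu_max` and `mu_min` per window.
#' @export
wt_extrema_mean <- function(theta, max_at, min_at, min_q = NULL, max_q = NULL) {
  stopifnot(is.finite(max_at), is.finite(min_at))
  no_q <- is.null(min_q) && is.null(max_q)
  if (no_q && (theta$theta2 != 0 || theta$theta2p != 0)) {
    stop("discharge slopes must be 0 when no discharge extrema are supplied")
  }
  qmin <- if (no_q) 0 else min_q
  qmax <- if (no_q) 0 else max_q
  list(mu_max = theta$theta0  + theta$theta1  * max_at + theta$theta2  * qmin,
       mu_min = theta$theta0p + theta$theta1p * min_at + theta$theta2p * qmax)
}

#' Construct and validate the link parameters
#'
#' @param theta0,theta1,theta2 intercept, AT slope and log-Q slope of the
#'   window-maximum regression.
#' @param theta0p,theta1p,theta2p the same for the window-minimum regression.
#' @param sigma_max,sigma_min residual standard deviations (degC), `> 0`.
#' @return a validated plain list, class `stm_link`.
#' @export
link_params <- function(theta0, theta1, theta2 = 0, theta0p = theta0, theta1p = theta1,
                        theta2p = 0, sigma_max, sigma_min) {
  if (sigma_max <= 0 || sigma_min <= 0) stop("sigma_max and sigma_min must be positive")
  structure(list(theta0 = theta0, theta1 = theta1, theta2 = theta2,
                 theta0p = theta0p, theta1p = theta1p, theta2p = theta2p,
                 sigma_max = sigma_max, sigma_min = sigma_min),
            class = "stm_link")
}

#' Daily residual link (model M2)
#'
#' Under M2 the mean daily WT deviation is
#' `delta * eps_AT + gamma * eps_Q * sin(2*pi/n * (doy - t0 + n/2))`; the flow
#' modifier is in strict antiphase with the WT seasonal signal, so it equals -1
#' at the WT seasonal maximum (high flow cools in summer) and +1 at the minimum
#' (high flow warms in winter). The realized deviation adds white noise
#' `zeta ~ N(0, sigma_zeta^2)`.
#'
#' @param link list with `delta`, `gamma`, `sigma_zeta` (gamma must be 0 when
#'   no discharge residuals are supplied).
#' @param eps_at daily AT residuals.
#' @param eps_q daily log-discharge residuals, or `NULL` without discharge.
#' @param doy day of year for each residual (1-based).
#' @param t0 phase of the *WT* seasonal signal (days).
#' @param n days in the calendar year (365 or 366), scalar or per-day vector.
#' @return numeric vector: the mean WT daily deviation.
#' @export
short_term_link <- function(link, eps_at, eps_q, doy, t0, n) {
  if (is.null(eps_q) || length(eps_q) == 0L) {
    if (link$gamma != 0) stop("gamma must be 0 when no discharge residuals are supplied")
    eps_q <- 0
  } else if (length(eps_q) != length(eps_at)) {
    stop("eps_at and eps_q lengths differ")
  }
  link$delta * eps_at + link$gamma * eps_q * flow_modifier(doy, t0, n)
}

# sin(2*pi/n * (doy - t0 + n/2)): antiphases the WT seasonal sinusoid
flow_modifier <- function(doy, t0, n) sin(2 * pi / n * (doy - t0 + n / 2))
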