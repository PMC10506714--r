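#' Define a simulation scenario
#'
#' Describes a synthetic multi-year daily dataset generated forward from the
#' model's own structure: covariate window means and amplitudes drawn around
#' stated values (with optional linear trend on the means), AR1 covariate
#' residuals, WT window extrema from the link regression, and daily WT from the
#' seasonal signal plus either the residual link with white noise (M2) or an
#' AR1 process (M1). The default scenario mimics a temperate Atlantic river of
#' medium size: 13 years, WT mean about 12.9 degC, AT mean about 12.4 degC,
#' log-discharge mean about 1.6 (about 5 m3/s), daily link gains delta = 0.6
#' and gamma = 0.5, and about 27% of WT days missing in multi-week gaps with
#' short sparse gaps on the covariates.
#'
#' @param years number of calendar years (series runs Jan 1 to Dec 31).
#' @param start_year first calendar year.
#' @param variant `"m2"` or `"m1"` (daily WT residual law).
#' @param use_discharge include a log-discharge covariate.
#' @param at,q lists with `alpha_mean`, `alpha_sd` (between-window SD),
#'   `alpha_trend` (degC per window, applied to the means), `beta_mean`,
#'   `beta_sd`, `t0`, `rho`, `sigma`.
#' @param link list with the six regression coefficients and `sigma_max`,
#'   `sigma_min`.
#' @param wt list with `t0` plus `delta`, `gamma`, `sigma_zeta` (M2) or
#'   `rho`, `sigma` (M1).
#' @param missing list with per-series missing fractions `wt`, `at`, `q` and
#'   mean gap lengths `gap_wt`, `gap_at`, `gap_q` (days).
#' @return list of class `stm_scenario`.
#' @export
stm_scenario <- function(years = 13, start_year = 1995,
                         variant = c("m2", "m1"), use_discharge = TRUE,
                         at = list(), q = list(), link = list(), wt = list(),
                         missing = list()) {
  variant <- match.arg(variant)
  at <- modifyList(list(alpha_mean = 12.4, alpha_sd = 0.5, alpha_trend = 0,
                        beta_mean = 6, beta_sd = 0.3, t0 = 113,
                        rho = 0.7, sigma = 1.5), at)
  q <- modifyList(list(alpha_mean = 1.6, alpha_sd = 0.3, alpha_trend = 0,
                       beta_mean = 1, beta_sd = 0.15, t0 = 295.5,
                       rho = 0.9, sigma = 0.15), q)
  link <- modifyList(list(theta0 = 3, theta1 = 0.8, theta2 = -0.2,
                          theta0p = 2.9, theta1p = 0.7, theta2p = 0.2,
                          sigma_max = 0.5, sigma_min = 0.5), link)
  wt_def <- if (variant == "m1") list(t0 = 113, rho = 0.8, sigma = 0.8)
            else list(t0 = 113, delta = 0.6, gamma = 0.5, sigma_zeta = 0.5)
  wt <- modifyList(wt_def, wt)
  missing <- modifyList(list(wt = 0.27, at = 0.006, q = 0.01,
                             gap_wt = 30, gap_at = 3, gap_q = 3), missing)
  if (!use_discharge) {
    q <- NULL
    link$theta2 <- 0; link$theta2p <- 0
    if (variant == "m2") wt$gamma <- 0
  }
  sc <- list(years = years, start_year = start_year, variant = variant,
             use_discharge = use_discharge, at = at, q = q, link = link,
             wt = wt, missing = missing)
  validate_scenario(sc)
  structure(sc, class = "stm_scenario")
}

validate_scenario <- function(sc) {
  stopifnot(sc$years >= 1)
  chk_cov <- function(p, nm) {
    if (abs(p$rho) >= 1) stop(nm, ": |rho| must be < 1")
    if (p$sigma <= 0) stop(nm, ": sigma must be positive")
    if (p$beta_mean < 0) stop(nm, ": beta_mean must be nonnegative")
    if (p$t0 < 0 || p$t0 >= 366) stop(nm, ": t0 must lie in [0, 366)")
  }
  chk_cov(sc$at, "at")
  if (sc$use_discharge) chk_cov(sc$q, "q")
  if (sc$link$sigma_max <= 0 || sc$link$sigma_min <= 0) {
    stop("link: sigma_max and sigma_min must be positive")
  }
  if (sc$variant == "m1") {
    if (abs(sc$wt$rho) >= 1 || sc$wt$sigma <= 0) stop("wt: invalid AR1 parameters")
  } else if (sc$wt$sigma_zeta <= 0) {
    stop("wt: sigma_zeta must be positive")
  }
  for (f in c("wt", "at", "q")) {
    if (sc$missing[[f]] < 0 || sc$missing[[f]] >= 1) {
      stop("missing fraction for ", f, " must lie in [0, 1)")
    }
  }
  invisible(sc)
}

#' Simulate a synthetic dataset with known parameters
#'
#' Runs the model forward under a scenario and returns both the dataset (with
#' missingness applied) and the full truth record, so inference can be checked
#' against the generating values. The draw is reproducible for a given seed.
#'
#' @param scenario an [stm_scenario()].
#' @param seed integer seed.
#' @return list with
#'   \describe{
#'     \item{data}{an `stm_data` ready for [stm_fit()].}
#'     \item{truth}{parameter list in the [joint_logposterior()] layout, with
#'       the realized per-window values, plus `full` (complete series before
#'       missingness) and the realized daily residuals.}
#'   }
#' @export
simulate_dataset <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "stm_scenario"))
  set.seed(as.integer(seed))
  dates <- seq(as.Date(sprintf("%d-01-01", scenario$start_year)),
               as.Date(sprintf("%d-12-31", scenario$start_year + scenario$years - 1L)),
               by = "day")
  windows <- build_windows(dates)
  d <- windows$day
  W <- n_windows(windows)
  Tn <- length(dates)
  omega <- 2 * pi / d$n_year

  sim_cov <- function(p) {
    alpha <- rnorm(W, p$alpha_mean + p$alpha_trend * (seq_len(W) - 1), p$alpha_sd)
    beta <- abs(rnorm(W, p$beta_mean, p$beta_sd))
    eps <- ar1_simulate(Tn, p$rho, p$sigma)
    s <- alpha[d$win] + beta[d$win] * sin(omega * (d$doy - p$t0))
    list(values = s + eps, eps = eps,
         params = list(alpha = alpha, beta = beta, t0 = p$t0,
                       rho = p$rho, sigma = p$sigma))
  }
  at <- sim_cov(scenario$at)
  qv <- if (scenario$use_discharge) sim_cov(scenario$q)

  th <- do.call(link_params, scenario$link)
  mu <- wt_extrema_mean(th, max_at = at$params$alpha + at$params$beta,
                        min_at = at$params$alpha - at$params$beta,
                        min_q = if (scenario$use_discharge) qv$params$alpha - qv$params$beta,
                        max_q = if (scenario$use_discharge) qv$params$alpha + qv$params$beta)
  max_wt <- rnorm(W, mu$mu_max, th$sigma_max)
  min_wt <- rnorm(W, mu$mu_min, th$sigma_min)
  sp_wt <- from_extrema(structure(list(max = max_wt, min = min_wt), class = "stm_extrema"),
                        t0 = scenario$wt$t0)
  s_wt <- seasonal_signal(sp_wt, windows)

  if (scenario$variant == "m1") {
    eps_wt <- ar1_simulate(Tn, scenario$wt$rho, scenario$wt$sigma)
    wt_vals <- s_wt + eps_wt
    wt_par <- list(max = max_wt, min = min_wt, t0 = scenario$wt$t0,
                   rho = scenario$wt$rho, sigma = scenario$wt$sigma)
  } else {
    link_d <- list(delta = scenario$wt$delta, gamma = scenario$wt$gamma,
                   sigma_zeta = scenario$wt$sigma_zeta)
    mean_dev <- short_term_link(link_d, at$eps, if (scenario$use_discharge) qv$eps,
                                d$doy, scenario$wt$t0, d$n_year)
    eps_wt <- mean_dev + rnorm(Tn, 0, scenario$wt$sigma_zeta)
    wt_vals <- s_wt + eps_wt
    wt_par <- c(list(max = max_wt, min = min_wt, t0 = scenario$wt$t0), link_d)
    names(wt_par)[names(wt_par) == "sigma_zeta"] <- "sigma_zeta"
  }

  mk <- function(vals, frac, gap, kind, seed_off) {
    s <- daily_series(dates, vals, kind)
    apply_missingness(s, frac, mean_gap = gap, seed = seed + seed_off)
  }
  data <- stm_data(
    wt = mk(wt_vals, scenario$missing$wt, scenario$missing$gap_wt, "wt", 101L),
    at = mk(at$values, scenario$missing$at, scenario$missing$gap_at, "at", 202L),
    q = if (scenario$use_discharge)
      mk(qv$values, scenario$missing$q, scenario$missing$gap_q, "logq", 303L)
  )
  truth <- list(at = at$params, q = if (scenario$use_discharge) qv$params,
                wt = wt_par, link = th,
                full = list(wt = wt_vals, at = at$values,
                            q = if (scenario$use_discharge) qv$values),
                eps = list(wt = eps_wt, at = at$eps,
                           q = if (scenario$use_discharge) qv$eps))
  list(data = data, truth = truth)
}

#' Mask a fraction of a series with geometric gap lengths
#'
#' Alternates observed and missing runs with geometric lengths, choosing the
#' observed-run mean so the long-run missing fraction matches `fraction`.
#' Already-missing values stay missing.
#'
#' @param series an `stm_series`.
#' @param fraction target missing fraction in `[0, 1)`.
#' @param mean_gap mean missing-run length in days (>= 1).
#' @param seed optional integer; when given, masking is reproducible and the
#'   caller's RNG stream is left untouched.
#' @return the series with values masked to `NA`.
#' @export
apply_missingness <- function(series, fraction, mean_gap = 10, seed = NULL) {
  stopifnot(inherits(series, "stm_series"))
  if (fraction < 0 || fraction >= 1) stop("`fraction` must lie in [0, 1)")
  if (mean_gap < 1) stop("`mean_gap` must be >= 1")
  if (fraction == 0) return(series)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  n <- length(series$values)
  mean_obs <- mean_gap * (1 - fraction) / fraction
  mask <- logical(n)  # TRUE = masked
  pos <- 1L
  missing_run <- runif(1) < fraction  # stationary start
  while (pos <= n) {
    len <- 1L + stats::rgeom(1L, 1 / (if (missing_run) mean_gap else mean_obs))
    end <- min(pos + len - 1L, n)
    if (missing_run) mask[pos:end] <- TRUE
    pos <- end + 1L
    missing_run <- !missing_run
  }
  series$values[mask] <- NA_real_
  series$observed <- !is.na(series$values)
  if (!any(series$observed)) {
    # degenerate draw on a very short series: keep at least one observation
    keep <- sample.int(n, 1L)
    stop("missingness draw removed every observation; lower `fraction` (kept day would be ",
         format(series$dates[keep]), ")")
  }
  series
}
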