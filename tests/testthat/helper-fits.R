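# Shared fixtures for the test suite. Everything is generated in code; the
# heavier fits are cached per test run so several test files can reuse them.

.fit_cache <- new.env(parent = emptyenv())

# fast MCMC settings for unit tests (not the desk preset: unit tests check
# structure and point behaviour, not calibrated posterior quantiles)
quick_mcmc <- function(seed = 1, keep = 500, burnin = 800) {
  stm_mcmc("desk", n_burnin = burnin, n_keep = keep, seed = seed)
}

# small well-specified M2 dataset with discharge, used across files
shared_sim <- function() {
  if (is.null(.fit_cache$sim)) {
    sc <- stm_scenario(years = 3, start_year = 2001, missing = list(wt = 0.12))
    .fit_cache$sim <- simulate_dataset(sc, seed = 404)
  }
  .fit_cache$sim
}

shared_fit_m2 <- function() {
  if (is.null(.fit_cache$fit_m2)) {
    .fit_cache$fit_m2 <- stm_fit(shared_sim()$data, mcmc = quick_mcmc(seed = 11))
  }
  .fit_cache$fit_m2
}

# A hand-built fit object with fully controlled draws (M2, no discharge,
# two windows over one year, WT observed everywhere and constant). Used to
# exercise the evaluation machinery in closed-form corners.
make_fake_fit <- function(n_draws = 50, wt_value = 10, sigma_zeta = 0.5,
                          theta1 = 1, theta1p = 1) {
  dates <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  Tn <- length(dates)
  wt <- daily_series(dates, rep(wt_value, Tn), "wt")
  at <- daily_series(dates, rep(12, Tn), "at")
  data <- stm_data(wt = wt, at = at)
  W <- 2L
  nm <- c(sprintf("alpha_at[%d]", 1:W), sprintf("beta_at[%d]", 1:W),
          "t0_at", "rho_at", "sigma_at",
          sprintf("max_wt[%d]", 1:W), sprintf("min_wt[%d]", 1:W), "t0_wt",
          "theta0", "theta1", "theta0p", "theta1p", "sigma_max", "sigma_min",
          "delta", "sigma_zeta")
  m <- matrix(0, n_draws, length(nm), dimnames = list(NULL, nm))
  m[, sprintf("alpha_at[%d]", 1:W)] <- 12
  m[, "t0_at"] <- 113; m[, "rho_at"] <- 0.5; m[, "sigma_at"] <- 1
  m[, sprintf("max_wt[%d]", 1:W)] <- wt_value
  m[, sprintf("min_wt[%d]", 1:W)] <- wt_value
  m[, "t0_wt"] <- 113
  m[, "theta1"] <- theta1; m[, "theta1p"] <- theta1p
  m[, "sigma_max"] <- 0.5; m[, "sigma_min"] <- 0.5
  m[, "sigma_zeta"] <- sigma_zeta
  structure(list(
    draws = coda::mcmc.list(coda::mcmc(m)),
    latent = list(wt = matrix(0, n_draws, 0), at = matrix(0, n_draws, 0),
                  q = NULL, idx_wt = integer(0), idx_at = integer(0), idx_q = NULL),
    data = data,
    config = stm_config("m2", use_discharge = FALSE),
    mcmc = stm_mcmc("desk"),
    convergence = NULL
  ), class = "stm_fit")
}
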