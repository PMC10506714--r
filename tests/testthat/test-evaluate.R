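test_that("chi-square statistic follows its arithmetic definition", {
  expect_equal(chi2_stat(10, 8, 4), 1)
  expect_equal(chi2_stat(c(10, 6), c(8, 6), c(4, 1)), 1)
  expect_error(chi2_stat(10, 8, 0), "zero conditional variance")
})

test_that("data that equal their conditional mean give a p-value of one", {
  fit <- make_fake_fit(n_draws = 80, wt_value = 10, sigma_zeta = 0.5)
  chi <- chi2_discrepancy(fit)
  expect_equal(chi$chi2_obs, rep(0, 80))
  expect_equal(chi$p_value, 1)       # replicates almost surely exceed 0
})

test_that("the chi-square check is calibrated on a well-specified fit", {
  fit <- shared_fit_m2()
  chi <- chi2_discrepancy(fit, n_draws = 400)
  expect_gt(chi$p_value, 0.05)
  expect_lt(chi$p_value, 0.95)
  # the observed discrepancy is on the scale of the number of observed days
  expect_equal(median(chi$chi2_obs) / chi$n_obs, 1, tolerance = 0.25)
})

test_that("DIC decomposition and its degenerate cases are exact", {
  expect_error(dic_from_deviance(5, 5), "at least 2")
  d <- dic_from_deviance(rep(120, 10), 120)
  expect_equal(d$pD, 0)
  expect_equal(d$DIC, 120)
  set.seed(4)
  dev <- rnorm(500, 100, 3)
  d2 <- dic_from_deviance(dev, 95)
  expect_equal(d2$DIC, d2$deviance_mean + d2$pD)   # identity holds exactly
})

test_that("a conjugate Normal toy model has about one effective parameter", {
  # y ~ N(mu, 1), flat-ish prior: posterior mu ~ N(ybar, 1/n); the deviance
  # decomposition then counts pD = n * E[(mu - ybar)^2] = 1
  set.seed(11)
  n <- 50
  y <- rnorm(n, 3, 1)
  ybar <- mean(y)
  mu_draws <- rnorm(4000, ybar, sqrt(1 / n))
  dev <- vapply(mu_draws, function(mu) -2 * sum(dnorm(y, mu, 1, log = TRUE)), numeric(1))
  dev_hat <- -2 * sum(dnorm(y, mean(mu_draws), 1, log = TRUE))
  d <- dic_from_deviance(dev, dev_hat)
  expect_equal(d$pD, 1, tolerance = 0.15)
})

test_that("fit-level DIC matches an independently coded deviance", {
  fit <- shared_fit_m2()
  d <- stm_dic(fit, n_draws = 300)
  expect_equal(d$DIC, d$deviance_mean + d$pD)
  expect_gt(d$pD, 0)
  # oracle: recompute the deviance of one draw with explicit formulas
  m <- as.matrix(fit$draws)
  i <- 100L
  p <- m[i, ]
  day <- fit$data$windows$day
  W <- max(day$win)
  filled <- function(v, idx, lat) { if (length(idx)) v[idx] <- lat[i, ]; v }
  at <- filled(fit$data$at, fit$latent$idx_at, fit$latent$at)
  qv <- filled(fit$data$q, fit$latent$idx_q, fit$latent$q)
  om <- 2 * pi / day$n_year
  s_at <- p[sprintf("alpha_at[%d]", day$win)] +
    p[sprintf("beta_at[%d]", day$win)] * sin(om * (day$doy - p["t0_at"]))
  s_q <- p[sprintf("alpha_q[%d]", day$win)] +
    p[sprintf("beta_q[%d]", day$win)] * sin(om * (day$doy - p["t0_q"]))
  a_wt <- (p[sprintf("max_wt[%d]", day$win)] + p[sprintf("min_wt[%d]", day$win)]) / 2
  b_wt <- (p[sprintf("max_wt[%d]", day$win)] - p[sprintf("min_wt[%d]", day$win)]) / 2
  mu <- a_wt + b_wt * sin(om * (day$doy - p["t0_wt"])) +
    p["delta"] * (at - s_at) +
    p["gamma"] * (qv - s_q) * sin(om * (day$doy - p["t0_wt"] + day$n_year / 2))
  obs <- !is.na(fit$data$wt)
  dev_oracle <- -2 * sum(dnorm(fit$data$wt[obs], mu[obs], p["sigma_zeta"], log = TRUE))
  st <- streamtemp:::stacked_state(fit)
  mom <- streamtemp:::daily_moments(fit, st, i)
  dev_pkg <- -2 * sum(dnorm(fit$data$wt[obs], mom$e[obs], sqrt(mom$v[obs]), log = TRUE))
  expect_equal(dev_pkg, unname(dev_oracle), tolerance = 1e-8)
})

test_that("DIC ranks the generating model ahead of the misspecified one", {
  sim <- shared_sim()
  fit2 <- shared_fit_m2()
  fit1 <- stm_fit(sim$data, config = stm_config("m1"),
                  mcmc = quick_mcmc(seed = 14, keep = 300, burnin = 600))
  d2 <- stm_dic(fit2, n_draws = 300)
  d1 <- stm_dic(fit1, n_draws = 300)
  expect_lt(d2$DIC, d1$DIC)
})

test_that("cross-validation recovers the noise floor and rejects bad splits", {
  sc <- stm_scenario(years = 3, use_discharge = FALSE,
                     at = list(sigma = 0.5), link = list(sigma_max = 1e-3, sigma_min = 1e-3),
                     wt = list(sigma_zeta = 1e-3), missing = list(wt = 0, at = 0))
  sim <- simulate_dataset(sc, seed = 19)
  cv <- cross_validate(sim$data, mcmc = quick_mcmc(seed = 2, keep = 300, burnin = 600))
  expect_lt(cv$rmse, 0.1)            # essentially noise-free data forecast exactly
  expect_equal(cv$n_test, nrow(cv$forecast))
  expect_error(cross_validate(sim$data, train_fraction = 1.2), "strictly between")
  # a tail with no observed WT is rejected
  data2 <- sim$data
  data2$wt[(floor(2 / 3 * length(data2$dates)) + 1):length(data2$dates)] <- NA
  expect_error(cross_validate(data2), "no observed WT days")
})

test_that("mean and median point predictions give similar cross-validation scores", {
  sim <- shared_sim()
  mc <- quick_mcmc(seed = 23, keep = 400, burnin = 800)
  cv_mean <- cross_validate(sim$data, mcmc = mc)
  cv_med <- cross_validate(sim$data, mcmc = mc, point = "median")
  expect_lt(abs(cv_mean$rmse - cv_med$rmse) / cv_mean$rmse, 0.05)
})

test_that("half-year discrepancies vanish for perfect replicates and skip empty windows", {
  fit <- make_fake_fit(n_draws = 30, wt_value = 10, sigma_zeta = 1e-9)
  hy <- halfyear_discrepancy(fit)
  expect_equal(nrow(hy), 2L)
  expect_equal(hy$median, c(0, 0), tolerance = 1e-6)
  # mask one window entirely
  fit2 <- make_fake_fit(n_draws = 30)
  fit2$data$wt[fit2$data$windows$day$win == 2] <- NA_real_
  idx <- which(is.na(fit2$data$wt))
  fit2$latent$idx_wt <- idx
  fit2$latent$wt <- matrix(10, 30, length(idx))
  expect_warning(hy2 <- halfyear_discrepancy(fit2), "without observed WT")
  expect_equal(nrow(hy2), 1L)
})

test_that("half-year discrepancies are centred near zero on a well-specified fit", {
  fit <- shared_fit_m2()
  hy <- halfyear_discrepancy(fit, n_draws = 300)
  covered <- hy$q2.5 <= 0 & hy$q97.5 >= 0
  expect_gt(mean(covered), 0.8)
  expect_lt(max(abs(hy$median)), 0.3)
})

test_that("the diagnostics table mirrors the assessment columns", {
  fit <- shared_fit_m2()
  tab <- diagnostics_table(list(m2 = fit), n_draws = 100)
  expect_equal(names(tab), c("model", "rmse", "chi2_pvalue", "deviance", "pD", "DIC"))
  expect_true(is.na(tab$rmse))
  expect_equal(tab$DIC, tab$deviance + tab$pD)
})
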