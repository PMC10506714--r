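test_that("fits are bit-reproducible for a fixed seed", {
  sc <- stm_scenario(years = 2, missing = list(wt = 0.1))
  sim <- simulate_dataset(sc, seed = 8)
  mc <- quick_mcmc(seed = 31, keep = 120, burnin = 150)
  f1 <- stm_fit(sim$data, mcmc = mc)
  f2 <- stm_fit(sim$data, mcmc = mc)
  expect_identical(as.matrix(f1$draws), as.matrix(f2$draws))
  expect_identical(f1$latent$wt, f2$latent$wt)
  f3 <- stm_fit(sim$data, mcmc = quick_mcmc(seed = 32, keep = 120, burnin = 150))
  expect_false(identical(as.matrix(f1$draws), as.matrix(f3$draws)))
})

test_that("discharge-free fits carry no discharge parameters", {
  sc <- stm_scenario(years = 2, use_discharge = FALSE, missing = list(wt = 0.1))
  sim <- simulate_dataset(sc, seed = 4)
  fit <- stm_fit(sim$data, mcmc = quick_mcmc(seed = 3, keep = 100, burnin = 150))
  nm <- colnames(as.matrix(fit$draws))
  expect_false(any(c("gamma", "theta2", "theta2p", "rho_q", "sigma_q") %in% nm))
  expect_true(all(c("delta", "theta1", "theta1p", "sigma_zeta") %in% nm))
})

test_that("posterior draws respect the model invariants", {
  fit <- shared_fit_m2()
  m <- as.matrix(fit$draws)
  W <- 6
  beta_at <- m[, sprintf("beta_at[%d]", 1:W)]
  beta_wt <- (m[, sprintf("max_wt[%d]", 1:W)] - m[, sprintf("min_wt[%d]", 1:W)]) / 2
  expect_true(all(beta_at >= 0))
  expect_true(all(beta_wt >= 0))
  expect_true(all(abs(m[, c("rho_at", "rho_q")]) < 1))
  expect_true(all(m[, c("sigma_at", "sigma_q", "sigma_zeta", "sigma_max", "sigma_min")] > 0))
  expect_true(all(m[, c("t0_at", "t0_q", "t0_wt")] >= 0 &
                  m[, c("t0_at", "t0_q", "t0_wt")] < 365))
  expect_true(all(is.finite(m)))
})

test_that("insufficient WT/covariate overlap is rejected", {
  dates <- seq(as.Date("2001-01-01"), as.Date("2002-12-31"), by = "day")
  at <- daily_series(dates, 10 + 6 * sin(2 * pi / 365 * (seq_along(dates) - 113)), "at")
  wt_vals <- rep(NA_real_, length(dates)); wt_vals[1:100] <- 8
  wt <- daily_series(dates, wt_vals, "wt")
  expect_error(stm_fit(stm_data(wt, at)), "at least 2 full windows")
})

test_that("posterior means approach the generating gains on low-noise data", {
  sc <- stm_scenario(years = 4, wt = list(sigma_zeta = 0.1),
                     missing = list(wt = 0.05))
  sim <- simulate_dataset(sc, seed = 17)
  fit <- stm_fit(sim$data, mcmc = quick_mcmc(seed = 5, keep = 800, burnin = 1500))
  m <- colMeans(as.matrix(fit$draws))
  expect_lt(abs(m["delta"] - 0.6), 0.1)
  expect_lt(abs(m["gamma"] - 0.5), 0.1)
  expect_lt(abs(m["rho_at"] - 0.7), 0.1)
})

test_that("the shared-intercept configuration drops theta0p from the draws", {
  sim <- shared_sim()
  fit <- stm_fit(sim$data, config = stm_config("m2", shared_intercept = TRUE),
                 mcmc = quick_mcmc(seed = 6, keep = 100, burnin = 200))
  nm <- colnames(as.matrix(fit$draws))
  expect_false("theta0p" %in% nm)
  expect_true("theta0" %in% nm)
})

test_that("an M1 fit on link-generated data absorbs the link into WT autocorrelation", {
  sim <- shared_sim()   # generated under M2 (delta = 0.6)
  fit <- stm_fit(sim$data, config = stm_config("m1"),
                 mcmc = quick_mcmc(seed = 9, keep = 300, burnin = 500))
  rho_wt <- as.matrix(fit$draws)[, "rho_wt"]
  expect_gt(mean(rho_wt), 0.2)        # posterior mass well away from 0
  expect_gt(quantile(rho_wt, 0.05), 0)
})

test_that("the sampler agrees with an independent JAGS implementation", {
  skip_if_not_installed("rjags")
  sc <- stm_scenario(years = 2, use_discharge = FALSE,
                     missing = list(wt = 0, at = 0))
  sim <- simulate_dataset(sc, seed = 12)
  data <- sim$data
  fit <- stm_fit(data, mcmc = quick_mcmc(seed = 21, keep = 1500, burnin = 1500))
  mine <- colMeans(as.matrix(fit$draws))

  d <- data$windows$day
  W <- max(d$win)
  emp_alpha <- as.numeric(tapply(data$at, d$win, mean))
  pr <- fit$priors
  model <- "
  model {
    for (w in 1:W) {
      alphaAT[w] ~ dnorm(empA[w], 0.01)
      betaAT[w] ~ dnorm(0, 0.01) T(0,)
      minWT[w] ~ dnorm(th0p + th1p * (alphaAT[w] - betaAT[w]), tauMin)
      maxWT[w] ~ dnorm(th0 + th1 * (alphaAT[w] + betaAT[w]), tauMax)
    }
    for (t in 1:T) {
      sAT[t] <- alphaAT[win[t]] + betaAT[win[t]] * sin(6.283185307179586 / nyr[t] * (doy[t] - t0AT))
      epsAT[t] <- AT[t] - sAT[t]
      sWT[t] <- 0.5 * (1 + sin(6.283185307179586 / nyr[t] * (doy[t] - t0WT))) * maxWT[win[t]] +
                0.5 * (1 - sin(6.283185307179586 / nyr[t] * (doy[t] - t0WT))) * minWT[win[t]]
      WT[t] ~ dnorm(sWT[t] + delta * epsAT[t], tauZ)
    }
    AT[1] ~ dnorm(sAT[1], tauAT * (1 - rhoAT^2))
    for (t in 2:T) { AT[t] ~ dnorm(sAT[t] + rhoAT * epsAT[t-1], tauAT) }
    t0AT ~ dunif(0, 365); t0WT ~ dunif(0, 365)
    rhoAT ~ dunif(-1, 1)
    tauAT <- pow(sigAT, -2); sigAT ~ dnorm(0, pAT) T(0,)
    tauZ <- pow(sigZ, -2); sigZ ~ dnorm(0, pZ) T(0,)
    tauMax <- pow(sigMax, -2); sigMax ~ dnorm(0, pMax) T(0,)
    tauMin <- pow(sigMin, -2); sigMin ~ dnorm(0, pMin) T(0,)
    th0 ~ dnorm(0, 0.01); th1 ~ dnorm(0, 0.01)
    th0p ~ dnorm(0, 0.01); th1p ~ dnorm(0, 0.01)
    delta ~ dnorm(0, 0.01)
  }"
  jd <- list(AT = data$at, WT = data$wt, T = length(data$dates), W = W,
             win = d$win, doy = d$doy, nyr = d$n_year, empA = emp_alpha,
             pAT = 1 / pr$sigma_at$sd^2, pZ = 1 / pr$sigma_zeta$sd^2,
             pMax = 1 / pr$sigma_max$sd^2, pMin = 1 / pr$sigma_min$sd^2)
  ini <- list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1,
              t0AT = 113, t0WT = 113, rhoAT = 0.5, delta = 0.5)
  mod <- rjags::jags.model(textConnection(model), data = jd, inits = ini,
                           n.chains = 1, n.adapt = 300, quiet = TRUE)
  update(mod, 700)
  js <- rjags::coda.samples(mod, c("delta", "sigZ", "rhoAT", "sigAT", "th1", "t0WT"),
                            n.iter = 1500)
  jmeans <- colMeans(as.matrix(js))
  expect_lt(abs(mine["delta"] - jmeans["delta"]), 0.02)
  expect_lt(abs(mine["sigma_zeta"] - jmeans["sigZ"]), 0.02)
  expect_lt(abs(mine["sigma_at"] - jmeans["sigAT"]), 0.03)
  expect_lt(abs(mine["rho_at"] - jmeans["rhoAT"]), 0.03)
  expect_lt(abs(mine["t0_wt"] - jmeans["t0WT"]), 1.5)
  expect_lt(abs(mine["theta1"] - jmeans["th1"]), 0.3)
})
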