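test_that("simulated covariate residuals match the stationary AR1 moments", {
  sc <- stm_scenario(years = 30, variant = "m2", use_discharge = FALSE,
                     missing = list(wt = 0, at = 0))
  sim <- simulate_dataset(sc, seed = 3)
  eps <- sim$truth$eps$at
  expect_equal(var(eps), sc$at$sigma^2 / (1 - sc$at$rho^2), tolerance = 0.05)
  expect_equal(unname(acf(eps, lag.max = 1, plot = FALSE)$acf[2]), sc$at$rho,
               tolerance = 0.03)
  expect_lt(abs(mean(eps)), 0.1)
})

test_that("daily WT residuals regress on AT residuals with slope delta", {
  # noise-free link: the WT/AT daily-residual regression recovers delta exactly
  sc0 <- stm_scenario(years = 6, use_discharge = FALSE,
                      wt = list(sigma_zeta = 1e-9),
                      missing = list(wt = 0, at = 0))
  sim0 <- simulate_dataset(sc0, seed = 9)
  slope <- coef(lm(sim0$truth$eps$wt ~ sim0$truth$eps$at - 1))[1]
  expect_equal(unname(slope), 0.6, tolerance = 1e-6)
  # with the white-noise term the least-squares slope stays near delta
  sc <- stm_scenario(years = 6, use_discharge = FALSE, missing = list(wt = 0, at = 0))
  sim <- simulate_dataset(sc, seed = 9)
  slope <- coef(lm(sim$truth$eps$wt ~ sim$truth$eps$at - 1))[1]
  expect_equal(unname(slope), 0.6, tolerance = 0.05)
})

test_that("residual correlation follows the closed-form gain identity", {
  # with discharge but no white noise, cor(eps_wt, eps_at) equals
  # delta * sd(eps_at) / sd(eps_wt) up to the finite-sample AT/Q cross term
  sc <- stm_scenario(years = 10, wt = list(sigma_zeta = 1e-9),
                     missing = list(wt = 0, at = 0, q = 0))
  sim <- simulate_dataset(sc, seed = 21)
  e_wt <- sim$truth$eps$wt; e_at <- sim$truth$eps$at
  expect_equal(cor(e_wt, e_at), 0.6 * sd(e_at) / sd(e_wt), tolerance = 0.02)
})

test_that("six-month means of simulated WT track the seasonal window means", {
  sc <- stm_scenario(years = 8, missing = list(wt = 0, at = 0, q = 0))
  sim <- simulate_dataset(sc, seed = 13)
  d <- sim$data$windows$day
  tr <- sim$truth$wt
  s_wt <- seasonal_signal(seasonal_params((tr$max + tr$min) / 2,
                                          (tr$max - tr$min) / 2, tr$t0),
                          sim$data$windows)
  win_means <- as.numeric(tapply(sim$truth$full$wt, d$win, mean))
  seas_means <- as.numeric(tapply(s_wt, d$win, mean))
  # residual window averages: the AR1 structure inflates the window-mean sd
  # to about 0.2-0.3 degC, so the max over 16 windows stays below ~3 sd
  expect_lt(max(abs(win_means - seas_means)), 0.8)
  expect_lt(mean(abs(win_means - seas_means)), 0.3)
  # the seasonal window mean is alpha plus the window average of the sine,
  # which stays well below the amplitude for calendar half-year windows
  alpha_wt <- (tr$max + tr$min) / 2
  expect_lt(max(abs(seas_means - alpha_wt)) / mean((tr$max - tr$min) / 2), 0.3)
})

test_that("simulation is reproducible and respects structural switches", {
  sc <- stm_scenario(years = 2)
  a <- simulate_dataset(sc, seed = 5); b <- simulate_dataset(sc, seed = 5)
  expect_identical(a$data$wt, b$data$wt)
  expect_identical(a$truth$link, b$truth$link)
  noq <- simulate_dataset(stm_scenario(years = 2, use_discharge = FALSE), seed = 5)
  expect_false(noq$data$use_discharge)
  expect_null(noq$truth$q)
  expect_identical(noq$truth$wt$gamma, 0)
  expect_identical(noq$truth$link$theta2, 0)
  m1 <- simulate_dataset(stm_scenario(years = 2, variant = "m1"), seed = 5)
  expect_true(all(c("rho", "sigma") %in% names(m1$truth$wt)))
  expect_error(stm_scenario(years = 2, at = list(rho = 1.1)), "rho")
  expect_error(stm_scenario(years = 2, missing = list(wt = 1)), "fraction")
})

test_that("noise-free simulation is exactly reconstructable from the truth", {
  sc <- stm_scenario(years = 2, use_discharge = TRUE,
                     at = list(sigma = 1e-9), q = list(sigma = 1e-9),
                     link = list(sigma_max = 1e-9, sigma_min = 1e-9),
                     wt = list(sigma_zeta = 1e-9),
                     missing = list(wt = 0, at = 0, q = 0))
  sim <- simulate_dataset(sc, seed = 2)
  tr <- sim$truth
  d <- sim$data$windows$day
  s_wt <- seasonal_signal(seasonal_params((tr$wt$max + tr$wt$min) / 2,
                                          (tr$wt$max - tr$wt$min) / 2, tr$wt$t0),
                          sim$data$windows)
  expect_equal(sim$data$wt, s_wt, tolerance = 1e-6)
})

test_that("missingness generator hits the requested fraction and gap law", {
  dates <- seq(as.Date("1995-01-01"), by = "day", length.out = 4745)
  ser <- daily_series(dates, rnorm(4745, 10, 2), "wt")
  expect_identical(apply_missingness(ser, 0, seed = 1)$observed, ser$observed)
  fr <- vapply(1:50, function(s) {
    mean(is.na(apply_missingness(ser, 0.27, mean_gap = 30, seed = s)$values))
  }, numeric(1))
  # long-run target 0.27; per-seed spread reflects ~20 geometric gap runs
  expect_equal(mean(fr), 0.27, tolerance = 0.075)
  expect_true(all(fr > 0.1 & fr < 0.5))
  gaps <- unlist(lapply(1:30, function(s) {
    r <- rle(is.na(apply_missingness(ser, 0.3, mean_gap = 30, seed = s)$values))
    r$lengths[r$values]
  }))
  expect_equal(mean(gaps), 30, tolerance = 0.1)
  expect_error(apply_missingness(ser, 1), "fraction")
  expect_error(apply_missingness(ser, 0.5, mean_gap = 0.2), "mean_gap")
  # seeded masking leaves the caller's RNG stream untouched
  set.seed(77); before <- rnorm(1)
  set.seed(77); invisible(apply_missingness(ser, 0.2, seed = 4)); after <- rnorm(1)
  expect_identical(before, after)
})
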