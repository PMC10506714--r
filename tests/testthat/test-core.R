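test_that("seasonal signal hits mean, mean+amplitude and mean-amplitude at the quarter points", {
  dates <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  w <- build_windows(dates)
  t0 <- 40
  sp <- seasonal_params(alpha = c(10, 10), beta = c(5, 5), t0 = t0)
  at_doy <- function(doy) seasonal_signal(sp, w, t = doy)  # doy == day index here
  expect_equal(at_doy(t0), 10)
  # the evaluator works on whole days; the nearest days to the quarter points
  # sit within 0.25 day of the exact extremum, where the sinusoid is flat
  expect_equal(at_doy(round(t0 + 365 / 4)), 15, tolerance = 1e-3)
  expect_equal(at_doy(round(t0 + 3 * 365 / 4)), 5, tolerance = 1e-3)
  expect_error(seasonal_signal(sp, w, t = 400), "outside")
})

test_that("seasonal signal is periodic over one year with fixed parameters", {
  dates <- seq(as.Date("2001-01-01"), as.Date("2002-12-31"), by = "day")
  w <- build_windows(dates)
  sp <- seasonal_params(alpha = rep(7, 4), beta = rep(3, 4), t0 = 200)
  v <- seasonal_signal(sp, w)
  expect_equal(v[1:365], v[366 + (0:364)], tolerance = 1e-12)
})

test_that("extrema reparametrization is an exact involution", {
  sp <- seasonal_params(alpha = c(10, 7, 0.25), beta = c(5, 0, 1.3), t0 = 12.5)
  ep <- to_extrema(sp)
  expect_identical(ep$max, c(15, 7, 1.55))
  expect_identical(ep$min, c(5, 7, -1.05))
  back <- from_extrema(ep, t0 = sp$t0)
  expect_identical(back$alpha, sp$alpha)   # bit-for-bit
  expect_identical(back$beta, sp$beta)
  # random roundtrips are exact up to one rounding of the intermediate sums
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(6, 10, 4); b <- abs(rnorm(6, 3, 2))
    sp2 <- seasonal_params(a, b, t0 = runif(1, 0, 365))
    back2 <- from_extrema(to_extrema(sp2), sp2$t0)
    expect_equal(back2$alpha, sp2$alpha, tolerance = 1e-15)
    expect_equal(back2$beta, sp2$beta, tolerance = 1e-15)
  }
  expect_error(from_extrema(structure(list(max = 1, min = 2), class = "stm_extrema"), 0),
               "max < min")
})

test_that("AR1 log-density matches white noise at rho = 0 and peaks at zero", {
  set.seed(2)
  eps <- rnorm(50, 0, 2)
  expect_equal(ar1_logdensity(eps, rho = 0, sigma = 2),
               sum(dnorm(eps, 0, 2, log = TRUE)))
  # all-zero path maximizes the zero-mean density
  for (rho in c(-0.5, 0, 0.8)) {
    lmax <- ar1_logdensity(rep(0, 30), rho, 1)
    for (i in 1:10) {
      expect_lt(ar1_logdensity(rnorm(30, 0, 0.5), rho, 1), lmax)
    }
  }
  expect_error(ar1_logdensity(eps, rho = 1, sigma = 1), "rho")
  expect_error(ar1_logdensity(eps, rho = 0.5, sigma = 0), "sigma")
})

test_that("AR1 simulation reproduces the stationary moments", {
  x <- ar1_simulate(1e5, rho = 0.8, sigma = 1, seed = 99)
  expect_equal(var(x), 1 / (1 - 0.8^2), tolerance = 0.02)
  expect_lt(abs(mean(x)), 0.05)
  # seed-reproducible
  expect_identical(x[1:10], ar1_simulate(10, 0.8, 1, seed = 99))
})

test_that("window extrema regression means follow the stated linear forms", {
  th <- link_params(theta0 = 2, theta1 = 0.7, theta2 = -0.5,
                    theta0p = 1, theta1p = 0.6, theta2p = 0.3,
                    sigma_max = 1, sigma_min = 1)
  mu <- wt_extrema_mean(th, max_at = 20, min_at = 5, min_q = 0, max_q = 2)
  expect_equal(mu$mu_max, 2 + 0.7 * 20 - 0.5 * 0)
  expect_equal(mu$mu_min, 1 + 0.6 * 5 + 0.3 * 2)
  # intercept-only
  th0 <- link_params(8, 0, 0, 8, 0, 0, sigma_max = 1, sigma_min = 1)
  expect_equal(wt_extrema_mean(th0, 20, 5, 0, 2), list(mu_max = 8, mu_min = 8))
  # discharge-free variant
  thq <- link_params(1, 0.5, 0, 1, 0.6, 0, sigma_max = 1, sigma_min = 1)
  expect_equal(wt_extrema_mean(thq, 10, 5)$mu_min, 1 + 0.6 * 5)
  thbad <- link_params(1, 0.5, 0.2, 1, 0.6, 0, sigma_max = 1, sigma_min = 1)
  expect_error(wt_extrema_mean(thbad, 10, 5), "discharge slopes")
  expect_error(link_params(1, 1, sigma_max = 0, sigma_min = 1), "positive")
})

test_that("the flow modifier strictly antiphases the WT seasonal cycle", {
  n <- 365; t0 <- 113
  # seasonal maximum at t0 + n/4, minimum at t0 + 3n/4
  expect_equal(streamtemp:::flow_modifier(t0 + n / 4, t0, n), -1)
  expect_equal(streamtemp:::flow_modifier(t0 + 3 * n / 4, t0, n), 1)
  link <- list(delta = 0.6, gamma = 0.5, sigma_zeta = 1)
  expect_equal(short_term_link(link, eps_at = 2, eps_q = 1,
                               doy = t0 + 3 * n / 4, t0 = t0, n = n), 1.7)
  expect_equal(short_term_link(link, eps_at = 2, eps_q = 1,
                               doy = t0 + n / 4, t0 = t0, n = n), 0.6 * 2 - 0.5)
  expect_error(short_term_link(link, eps_at = c(1, 2), eps_q = 1,
                               doy = 1:2, t0 = t0, n = n), "lengths differ")
  expect_error(short_term_link(link, eps_at = 1, eps_q = NULL,
                               doy = 1, t0 = t0, n = n), "gamma")
  link0 <- list(delta = 0.5, gamma = 0, sigma_zeta = 1)
  expect_equal(short_term_link(link0, eps_at = 2, eps_q = NULL,
                               doy = 1, t0 = t0, n = n), 1)
})

test_that("series containers validate values and alignment", {
  dates <- seq(as.Date("2001-01-01"), as.Date("2001-01-10"), by = "day")
  s <- daily_series(dates, c(1:9, NA), "wt")
  expect_equal(s$observed, c(rep(TRUE, 9), FALSE))
  expect_error(daily_series(dates, c(rep(1, 9), 60), "wt"), "sanity bounds")
  expect_error(daily_series(dates, 1:9, "wt"), "lengths differ")
  expect_no_error(daily_series(dates, rep(NA_real_, 10), "wt"))  # all-NA series ok
  expect_error(stm_data(wt = daily_series(dates, rep(NA_real_, 10), "wt"),
                        at = daily_series(dates, rep(5, 10), "at")),
               "no observed values")
})
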