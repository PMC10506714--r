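# The oracle implementation lives in helper-oracle.R: every Gaussian term of
# the joint density written out explicitly, independent of the package's
# seasonal/AR1 helpers, on a 30-day toy dataset small enough to enumerate.

test_that("joint log-posterior matches the term-by-term oracle on a 30-day toy", {
  for (useq in c(TRUE, FALSE)) for (variant in c("m2", "m1")) {
    data <- toy_data(use_discharge = useq)
    cfg <- stm_config(variant, use_discharge = useq)
    pr <- default_priors(data, cfg)
    # single partial window: per-window parameter vectors have length 1
    p <- toy_params(variant, useq)
    got <- joint_logposterior(data, p, pr, cfg)
    want <- oracle_lp(data, p, pr, variant, useq)
    expect_equal(got, want, tolerance = 1e-10,
                 label = paste("variant", variant, "useq", useq))
  }
})

test_that("latent values at gaps enter the density exactly like observations", {
  data <- toy_data(use_discharge = TRUE, gaps = TRUE)
  cfg <- stm_config("m2")
  pr <- default_priors(data, cfg)
  p <- toy_params("m2", TRUE)
  latent <- list(wt = c(8.8, 9.4), at = 7.7, q = 1.45)
  got <- joint_logposterior(data, p, pr, cfg, latent = latent)
  want <- oracle_lp(data, p, pr, "m2", TRUE, latent = latent)
  expect_equal(got, want, tolerance = 1e-10)
  # covariate gaps demand latent values
  expect_error(joint_logposterior(data, p, pr, cfg), "latent values required")
  # without latent WT the gap days contribute no likelihood term
  got2 <- joint_logposterior(data, p, pr, cfg,
                             latent = list(at = 7.7, q = 1.45))
  want2 <- oracle_lp(data, p, pr, "m2", TRUE,
                     latent = list(at = 7.7, q = 1.45))
  expect_equal(got2, want2, tolerance = 1e-10)
})

test_that("invalid parameter states yield -Inf rather than an error", {
  data <- toy_data()
  cfg <- stm_config("m2")
  pr <- default_priors(data, cfg)
  p <- toy_params()
  bad <- list(
    within(p, at$rho <- 1.2),
    within(p, at$sigma <- -1),
    within(p, at$beta <- -0.5),
    within(p, wt$sigma_zeta <- 0),
    within(p, link$sigma_max <- -2),
    within(p, wt$t0 <- 400)
  )
  for (b in bad) expect_identical(joint_logposterior(data, b, pr, cfg), -Inf)
})

test_that("M2 with zero link gains collapses to M1 with zero WT autocorrelation", {
  data <- toy_data(use_discharge = TRUE)
  pr2 <- default_priors(data, stm_config("m2"))
  pr1 <- default_priors(data, stm_config("m1"))
  p_base <- toy_params("m2")
  p2a <- within(p_base, { wt$delta <- 0; wt$gamma <- 0; wt$sigma_zeta <- 0.55 })
  p2b <- within(p2a, { wt$max <- 13.0; wt$min <- 5.5 })
  m1a <- toy_params("m1"); m1a$wt$rho <- 0; m1a$wt$sigma <- 0.55
  m1b <- within(m1a, { wt$max <- 13.0; wt$min <- 5.5 })
  # identical likelihoods up to the (constant) prior terms that differ between
  # the variants, so log-posterior *differences* agree exactly
  d2 <- joint_logposterior(data, p2a, pr2, stm_config("m2")) -
        joint_logposterior(data, p2b, pr2, stm_config("m2"))
  d1 <- joint_logposterior(data, m1a, pr1, stm_config("m1")) -
        joint_logposterior(data, m1b, pr1, stm_config("m1"))
  expect_equal(d2, d1, tolerance = 1e-10)
})

test_that("the shared-intercept variant ties theta0p to theta0", {
  data <- toy_data()
  cfg <- stm_config("m2", shared_intercept = TRUE)
  pr <- default_priors(data, cfg)
  p <- toy_params()
  expect_error(joint_logposterior(data, p, pr, cfg), "theta0p == theta0")
  p$link$theta0p <- p$link$theta0
  lp_shared <- joint_logposterior(data, p, pr, cfg)
  lp_free <- joint_logposterior(data, p, pr, stm_config("m2"))
  # one fewer free coefficient: densities differ by exactly its prior term
  expect_equal(lp_shared - lp_free,
               -dnorm(p$link$theta0, 0, pr$theta$sd, log = TRUE),
               tolerance = 1e-10)
})
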