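# The joint log-posterior is checked against an oracle that writes every
# Gaussian term out explicitly (independent of the package's seasonal/AR1
# helpers), on a 30-day toy dataset small enough to enumerate.

toy_data <- function(use_discharge = TRUE, gaps = FALSE) {
  dates <- seq(as.Date("2001-03-01"), by = "day", length.out = 30)
  set.seed(7)
  at <- 8 + 4 * sin(2 * pi / 365 * (60:89 - 100)) + rnorm(30, 0, 1)
  wt <- 9 + 3 * sin(2 * pi / 365 * (60:89 - 110)) + rnorm(30, 0, 0.5)
  qv <- 1.5 + rnorm(30, 0, 0.2)
  if (gaps) { wt[c(4, 9)] <- NA; at[15] <- NA; qv[22] <- NA }
  stm_data(wt = daily_series(dates, wt, "wt"),
           at = daily_series(dates, at, "at"),
           q = if (use_discharge) daily_series(dates, qv, "logq"))
}

toy_params <- function(variant = "m2", use_discharge = TRUE) {
  p <- list(
    at = list(alpha = 8.2, beta = 4.1, t0 = 99, rho = 0.55, sigma = 1.1),
    q = if (use_discharge) list(alpha = 1.4, beta = 0.3, t0 = 280, rho = 0.8, sigma = 0.25),
    link = link_params(theta0 = 2.5, theta1 = 0.75, theta2 = if (use_discharge) -0.3 else 0,
                       theta0p = 2.1, theta1p = 0.65, theta2p = if (use_discharge) 0.25 else 0,
                       sigma_max = 0.6, sigma_min = 0.7),
    wt = if (variant == "m1") list(max = 12.4, min = 6.1, t0 = 108, rho = 0.6, sigma = 0.8)
         else list(max = 12.4, min = 6.1, t0 = 108, delta = 0.62,
                   gamma = if (use_discharge) 0.45 else 0, sigma_zeta = 0.55)
  )
  p
}

# fully written-out oracle: every density term typed independently
oracle_lp <- function(data, p, pr, variant, use_discharge, latent = NULL) {
  doy <- as.integer(format(data$dates, "%j"))
  n <- 365
  at <- data$at; wt <- data$wt; qv <- data$q
  if (!is.null(latent$at)) at[is.na(at)] <- latent$at
  if (!is.null(latent$wt)) wt[is.na(wt)] <- latent$wt
  if (use_discharge && !is.null(latent$q)) qv[is.na(qv)] <- latent$q

  lp <- 0
  ar1_terms <- function(x, mean_fun, rho, sigma) {
    e <- x - mean_fun
    s <- dnorm(e[1], 0, sigma / sqrt(1 - rho^2), log = TRUE)
    for (t in 2:length(e)) s <- s + dnorm(e[t], rho * e[t - 1], sigma, log = TRUE)
    s
  }
  s_at <- p$at$alpha + p$at$beta * sin(2 * pi / n * (doy - p$at$t0))
  lp <- lp + ar1_terms(at, s_at, p$at$rho, p$at$sigma)
  if (use_discharge) {
    s_q <- p$q$alpha + p$q$beta * sin(2 * pi / n * (doy - p$q$t0))
    lp <- lp + ar1_terms(qv, s_q, p$q$rho, p$q$sigma)
  }
  th <- p$link
  mu_max <- th$theta0 + th$theta1 * (p$at$alpha + p$at$beta) +
    (if (use_discharge) th$theta2 * (p$q$alpha - p$q$beta) else 0)
  mu_min <- th$theta0p + th$theta1p * (p$at$alpha - p$at$beta) +
    (if (use_discharge) th$theta2p * (p$q$alpha + p$q$beta) else 0)
  lp <- lp + dnorm(p$wt$max, mu_max, th$sigma_max, log = TRUE) +
             dnorm(p$wt$min, mu_min, th$sigma_min, log = TRUE)
  a_wt <- (p$wt$max + p$wt$min) / 2; b_wt <- (p$wt$max - p$wt$min) / 2
  s_wt <- a_wt + b_wt * sin(2 * pi / n * (doy - p$wt$t0))
  if (variant == "m1") {
    lp <- lp + ar1_terms(wt, s_wt, p$wt$rho, p$wt$sigma)
  } else {
    mod <- sin(2 * pi / n * (doy - p$wt$t0 + n / 2))
    mu <- s_wt + p$wt$delta * (at - s_at) +
      (if (use_discharge) p$wt$gamma * (qv - s_q) * mod else 0)
    use <- if (is.null(latent$wt)) !is.na(data$wt) else rep(TRUE, 30)
    lp <- lp + sum(dnorm(wt[use], mu[use], p$wt$sigma_zeta, log = TRUE))
  }
  # priors
  hn <- function(x, sd) dnorm(x, 0, sd, log = TRUE) + log(2)
  lp <- lp + dnorm(p$at$alpha, pr$alpha_at$mean, pr$alpha_at$sd, log = TRUE) +
    hn(p$at$beta, pr$beta_at$sd) + hn(p$at$sigma, pr$sigma_at$sd) -
    log(365) - log(2)
  if (use_discharge) {
    lp <- lp + dnorm(p$q$alpha, pr$alpha_q$mean, pr$alpha_q$sd, log = TRUE) +
      hn(p$q$beta, pr$beta_q$sd) + hn(p$q$sigma, pr$sigma_q$sd) - log(365) - log(2)
  }
  th_free <- c(th$theta0, th$theta1, if (use_discharge) th$theta2,
               th$theta0p, th$theta1p, if (use_discharge) th$theta2p)
  lp <- lp + sum(dnorm(th_free, 0, pr$theta$sd, log = TRUE)) +
    hn(th$sigma_max, pr$sigma_max$sd) + hn(th$sigma_min, pr$sigma_min$sd) - log(365)
  if (variant == "m1") {
    lp <- lp + hn(p$wt$sigma, pr$sigma_wt$sd) - log(2)
  } else {
    dg <- c(p$wt$delta, if (use_discharge) p$wt$gamma)
    lp <- lp + sum(dnorm(dg, 0, pr$deltagamma$sd, log = TRUE)) +
      hn(p$wt$sigma_zeta, pr$sigma_zeta$sd)
  }
  lp
}

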