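# Internal machinery to walk posterior draws and reconstruct, for each draw,
# the conditional mean and variance of WT on every day (given all parameters
# and the latent values of that draw). Under M2 the conditional law of day t is
# N(seasonal + delta*eps_at + gamma*eps_q*modifier, sigma_zeta^2); under M1 it
# is the AR1 one-step conditional N(seasonal + rho*(wt[t-1] - seasonal[t-1]),
# sigma^2) with the stationary law on the first day.

# stacked parameter draws + latent matrices, one row per kept draw
stacked_state <- function(fit) {
  list(par = as.matrix(fit$draws),
       lat_wt = fit$latent$wt, lat_at = fit$latent$at, lat_q = fit$latent$q)
}

# evenly-spaced subsample of draw indices (across the stacked chains)
draw_subsample <- function(n_total, n_draws) {
  if (is.null(n_draws) || n_draws >= n_total) return(seq_len(n_total))
  unique(round(seq(1, n_total, length.out = n_draws)))
}

# For draw i, return list(e = E[WT_t | theta], v = Var[WT_t | theta]) over all
# days, plus the filled series of that draw.
daily_moments <- function(fit, st, i) {
  p <- st$par[i, ]
  d <- fit$data$windows$day
  useq <- fit$config$use_discharge
  m1 <- fit$config$variant == "m1"
  W <- n_windows(fit$data$windows)
  omega <- 2 * pi / d$n_year

  at <- fit$data$at
  if (length(fit$latent$idx_at)) at[fit$latent$idx_at] <- st$lat_at[i, ]
  a_at <- p[sprintf("alpha_at[%d]", 1:W)]; b_at <- p[sprintf("beta_at[%d]", 1:W)]
  s_at <- a_at[d$win] + b_at[d$win] * sin(omega * (d$doy - p["t0_at"]))
  eps_at <- at - s_at

  eps_q <- NULL; qv <- NULL
  if (useq) {
    qv <- fit$data$q
    if (length(fit$latent$idx_q)) qv[fit$latent$idx_q] <- st$lat_q[i, ]
    a_q <- p[sprintf("alpha_q[%d]", 1:W)]; b_q <- p[sprintf("beta_q[%d]", 1:W)]
    s_q <- a_q[d$win] + b_q[d$win] * sin(omega * (d$doy - p["t0_q"]))
    eps_q <- qv - s_q
  }

  mxw <- p[sprintf("max_wt[%d]", 1:W)]; mnw <- p[sprintf("min_wt[%d]", 1:W)]
  mx <- mxw[d$win]; mn <- mnw[d$win]
  sn <- sin(omega * (d$doy - p["t0_wt"]))
  s_wt <- 0.5 * (1 + sn) * mx + 0.5 * (1 - sn) * mn

  wt_full <- fit$data$wt
  if (length(fit$latent$idx_wt)) wt_full[fit$latent$idx_wt] <- st$lat_wt[i, ]

  if (m1) {
    rho <- p["rho_wt"]; sig <- p["sigma_wt"]
    e <- s_wt; v <- rep(sig^2, length(s_wt))
    Tn <- length(s_wt)
    if (Tn > 1) {
      e[-1] <- s_wt[-1] + rho * (wt_full[-Tn] - s_wt[-Tn])
    }
    v[1] <- sig^2 / (1 - rho^2)
  } else {
    link <- list(delta = unname(p["delta"]),
                 gamma = if (useq) unname(p["gamma"]) else 0,
                 sigma_zeta = unname(p["sigma_zeta"]))
    e <- s_wt + short_term_link(link, eps_at, eps_q, d$doy, p["t0_wt"], d$n_year)
    v <- rep(link$sigma_zeta^2, length(e))
  }
  list(e = unname(e), v = unname(v), wt_full = wt_full,
       eps_at = unname(eps_at), eps_q = if (useq) unname(eps_q), s_wt = unname(s_wt))
}

# posterior mean of the stacked state, as a pseudo-draw (used for the DIC
# plug-in deviance)
posterior_mean_state <- function(st) {
  list(par = rbind(colMeans(st$par)),
       lat_wt = rbind(colMeans(st$lat_wt)),
       lat_at = rbind(colMeans(st$lat_at)),
       lat_q = if (!is.null(st$lat_q)) rbind(colMeans(st$lat_q)))
}
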