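#' Chi-square discrepancy statistic
#'
#' The building block of the posterior check:
#' `sum_t (y_t - e_t)^2 / v_t` for observations (or replicates) `y` against
#' conditional means `e` and variances `v`.
#'
#' @param y observed or replicated values.
#' @param e,v conditional means and variances (same length; `v > 0`).
#' @return the scalar discrepancy.
#' @export
chi2_stat <- function(y, e, v) {
  if (any(v <= 0)) stop("zero conditional variance at an observed day")
  sum((y - e)^2 / v)
}

#' Posterior-predictive chi-square discrepancy check
#'
#' For each posterior draw, computes the chi-square discrepancy
#' `sum_t (WT_t - E[WT_t | theta])^2 / Var[WT_t | theta]` over observed WT
#' days, both for the observations and for data replicated from the same
#' conditional law, and returns the Bayesian p-value: the probability that the
#' replicated discrepancy exceeds the observed one. Values near 0.5 indicate
#' congruency between model and data; values around 0.95 or 0.05 are serious
#' inconsistency warnings.
#'
#' @param fit an `stm_fit`.
#' @param n_draws number of (evenly subsampled) draws used; `NULL` for all.
#' @return list of class `stm_chi2` with `p_value`, per-draw vectors
#'   `chi2_obs` and `chi2_rep`, and `n_obs` (number of observed WT days used).
#' @export
chi2_discrepancy <- function(fit, n_draws = NULL) {
  stopifnot(inherits(fit, "stm_fit"))
  st <- stacked_state(fit)
  idx <- draw_subsample(nrow(st$par), n_draws)
  obs <- which(!is.na(fit$data$wt))
  y <- fit$data$wt[obs]
  chi_obs <- chi_rep <- numeric(length(idx))
  for (k in seq_along(idx)) {
    mom <- daily_moments(fit, st, idx[k])
    e <- mom$e[obs]; v <- mom$v[obs]
    chi_obs[k] <- chi2_stat(y, e, v)
    yrep <- rnorm(length(e), e, sqrt(v))
    chi_rep[k] <- chi2_stat(yrep, e, v)
  }
  structure(list(p_value = mean(chi_rep > chi_obs),
                 chi2_obs = chi_obs, chi2_rep = chi_rep, n_obs = length(obs)),
            class = "stm_chi2")
}

#' @export
print.stm_chi2 <- function(x, ...) {
  cat(sprintf("chi-square posterior check: Bayesian p-value %.3f (%d draws, %d observed days)\n",
              x$p_value, length(x$chi2_obs), x$n_obs))
  invisible(x)
}

#' Deviance Information Criterion
#'
#' `stm_dic()` computes, per posterior draw, the deviance
#' `-2 * log p(observed WT | theta)` (observed WT days only, so M1 and M2 are
#' compared on identical observations; covariate likelihood terms are
#' excluded), the plug-in deviance at the posterior mean of all parameters and
#' latent values, and the classic decomposition `pD = mean(D) - D(mean)`,
#' `DIC = mean(D) + pD`. `dic_from_deviance()` is the bare decomposition for
#' externally computed deviances.
#'
#' @param fit an `stm_fit`.
#' @param n_draws draws used for the deviance average; `NULL` for all.
#' @return list of class `stm_dic`: `deviance_mean`, `deviance_at_mean`, `pD`,
#'   `DIC`, and the per-draw `deviance` vector.
#' @export
stm_dic <- function(fit, n_draws = NULL) {
  stopifnot(inherits(fit, "stm_fit"))
  st <- stacked_state(fit)
  idx <- draw_subsample(nrow(st$par), n_draws)
  obs <- which(!is.na(fit$data$wt))
  y <- fit$data$wt[obs]
  dev <- vapply(idx, function(i) {
    mom <- daily_moments(fit, st, i)
    -2 * sum(dnorm(y, mom$e[obs], sqrt(mom$v[obs]), log = TRUE))
  }, numeric(1))
  stm <- posterior_mean_state(st)
  mom_hat <- daily_moments(fit, stm, 1L)
  dev_hat <- -2 * sum(dnorm(y, mom_hat$e[obs], sqrt(mom_hat$v[obs]), log = TRUE))
  out <- dic_from_deviance(dev, dev_hat)
  out$deviance <- dev
  structure(out, class = "stm_dic")
}

#' @rdname stm_dic
#' @param deviance per-draw deviance values (at least 2).
#' @param deviance_at_mean deviance at the posterior mean of the parameters.
#' @export
dic_from_deviance <- function(deviance, deviance_at_mean) {
  if (length(deviance) < 2) stop("DIC needs at least 2 deviance draws")
  dm <- mean(deviance)
  pD <- dm - deviance_at_mean
  list(deviance_mean = dm, deviance_at_mean = deviance_at_mean,
       pD = pD, DIC = dm + pD)
}

#' @export
print.stm_dic <- function(x, ...) {
  cat(sprintf("DIC %.1f (mean deviance %.1f, pD %.1f)\n", x$DIC, x$deviance_mean, x$pD))
  invisible(x)
}

#' Chronological cross-validation of forecasting skill
#'
#' Splits the series at `floor(train_fraction * T)` days, refits the model with
#' the tail WT masked (covariates keep their full span, so the tail WT days are
#' estimated as posterior-predictive latent values during the fit), and scores
#' the point predictions against the held-out observations with the root mean
#' square error.
#'
#' @param data an `stm_data`.
#' @param config an [stm_config()].
#' @param mcmc an [stm_mcmc()].
#' @param priors optional `stm_priors` (default: [default_priors()] on the
#'   training data).
#' @param train_fraction fraction of days used for training (default 2/3).
#' @param point `"mean"` (default) or `"median"` posterior point prediction.
#' @return list of class `stm_cv`: `rmse`, `n_test`, `split_date`, data.frame
#'   `forecast` (date, observed value, prediction and 95% bounds) and the
#'   training `fit`.
#' @export
cross_validate <- function(data, config = stm_config(), mcmc = stm_mcmc(),
                           priors = NULL, train_fraction = 2 / 3,
                           point = c("mean", "median")) {
  stopifnot(inherits(data, "stm_data"))
  point <- match.arg(point)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1")
  }
  Tn <- length(data$dates)
  n_train <- floor(train_fraction * Tn)
  tail_idx <- (n_train + 1L):Tn
  test_obs <- tail_idx[!is.na(data$wt[tail_idx])]
  if (length(test_obs) == 0) stop("no observed WT days in the held-out tail")
  train <- data
  train$wt[tail_idx] <- NA_real_
  fit <- stm_fit(train, config = config, priors = priors, mcmc = mcmc)
  pred <- predict(fit, target_days = data$dates[test_obs])
  pt <- if (point == "mean") pred$mean else pred$median
  err <- data$wt[test_obs] - pt
  structure(list(rmse = sqrt(mean(err^2)), n_test = length(test_obs),
                 split_date = data$dates[n_train],
                 forecast = data.frame(date = data$dates[test_obs],
                                       wt_obs = data$wt[test_obs],
                                       prediction = pt,
                                       q2.5 = pred$q2.5, q97.5 = pred$q97.5),
                 fit = fit),
            class = "stm_cv")
}

#' @export
print.stm_cv <- function(x, ...) {
  cat(sprintf("chronological cross-validation: RMSE %.3f degC over %d held-out days (split %s)\n",
              x$rmse, x$n_test, format(x$split_date)))
  invisible(x)
}

#' Replicated-vs-observed six-month mean discrepancies
#'
#' For each half-year window with observed WT, computes the posterior
#' distribution of the difference between the window mean of replicated data
#' and the window mean of the observations, using only observed days in both
#' terms. Well-calibrated fits give distributions centred on zero.
#'
#' @param fit an `stm_fit`.
#' @param n_draws draws used; `NULL` for all.
#' @return data.frame of class `stm_halfyear`: one row per retained window
#'   with the window descriptors, `median`, `q2.5`, `q25`, `q75`, `q97.5` of
#'   the discrepancy (degC) and `n_obs`. Windows without observed WT days are
#'   skipped with a warning.
#' @export
halfyear_discrepancy <- function(fit, n_draws = NULL) {
  stopifnot(inherits(fit, "stm_fit"))
  st <- stacked_state(fit)
  idx <- draw_subsample(nrow(st$par), n_draws)
  d <- fit$data$windows$day
  wdf <- fit$data$windows$window
  obs <- !is.na(fit$data$wt)
  keep <- vapply(wdf$win, function(w) any(obs[d$win == w]), logical(1))
  if (any(!keep)) {
    warning("skipping ", sum(!keep), " window(s) without observed WT days")
  }
  wins <- wdf$win[keep]
  obs_mean <- vapply(wins, function(w) mean(fit$data$wt[obs & d$win == w]), numeric(1))
  disc <- matrix(NA_real_, length(idx), length(wins))
  for (k in seq_along(idx)) {
    mom <- daily_moments(fit, st, idx[k])
    yrep <- rnorm(length(mom$e), mom$e, sqrt(mom$v))
    disc[k, ] <- vapply(seq_along(wins), function(j) {
      i <- obs & d$win == wins[j]
      mean(yrep[i])
    }, numeric(1)) - obs_mean
  }
  qs <- t(apply(disc, 2, quantile, c(0.025, 0.25, 0.5, 0.75, 0.975)))
  out <- data.frame(wdf[keep, c("win", "year", "half", "full")],
                    n_obs = vapply(wins, function(w) sum(obs[d$win == w]), integer(1)),
                    median = qs[, 3], q2.5 = qs[, 1], q25 = qs[, 2],
                    q75 = qs[, 4], q97.5 = qs[, 5], row.names = NULL)
  class(out) <- c("stm_halfyear", "data.frame")
  out
}

#' Model-assessment summary table
#'
#' Collects the fit diagnostics of one or more fitted models into a flat
#' table: chi-square Bayesian p-value, posterior mean deviance, pD and DIC,
#' plus (when cross-validation results are supplied) the forecast RMSE.
#'
#' @param fits named list of `stm_fit` objects (names become the model column).
#' @param cv optional named list of `stm_cv` results aligned with `fits`.
#' @param n_draws draws used for the posterior summaries; `NULL` for all.
#' @return data.frame with columns `model`, `rmse`, `chi2_pvalue`, `deviance`,
#'   `pD`, `DIC`.
#' @export
diagnostics_table <- function(fits, cv = NULL, n_draws = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1)
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  rows <- lapply(seq_along(fits), function(i) {
    chi <- chi2_discrepancy(fits[[i]], n_draws = n_draws)
    dic <- stm_dic(fits[[i]], n_draws = n_draws)
    data.frame(model = nm[i],
               rmse = if (!is.null(cv[[nm[i]]])) cv[[nm[i]]]$rmse else NA_real_,
               chi2_pvalue = chi$p_value, deviance = dic$deviance_mean,
               pD = dic$pD, DIC = dic$DIC)
  })
  do.call(rbind, rows)
}
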