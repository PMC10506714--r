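#' Posterior-predictive water-temperature estimates
#'
#' Summarizes the posterior-predictive distribution of daily WT at the
#' requested days. Estimation of unknown WT happens *during* the fit: any day
#' inside the dataset span where WT is missing (gaps, or hindcast/forecast
#' stretches appended to the covariate series before fitting) carries latent
#' posterior draws that propagate every source of uncertainty -- window
#' parameters, covariate decomposition, link regression and daily noise. Days
#' with observed WT are passed through unchanged and flagged as observed.
#'
#' To forecast beyond the fitted span, extend the covariate series (the AT and
#' Q inputs simply include the forecast period, with WT left missing) and
#' refit; the forecast days are then ordinary missing-WT days.
#'
#' @param object an `stm_fit`.
#' @param target_days `Date` vector of days to summarize (default: all days of
#'   the fitted dataset). Days outside the covariate-covered span are rejected,
#'   listing the missing days.
#' @param return_draws also attach the raw predictive draws matrix
#'   (draws x target days) as attribute `"draws"` (observed days appear as
#'   constant columns).
#' @param ... unused.
#' @return data.frame of class `stm_prediction`: `date`, `observed` (logical),
#'   `mean`, `median`, `q2.5`, `q25`, `q75`, `q97.5`.
#' @export
predict.stm_fit <- function(object, target_days = NULL, return_draws = FALSE, ...) {
  fit <- object
  if (is.null(target_days)) target_days <- fit$data$dates
  if (!inherits(target_days, "Date")) stop("`target_days` must be a Date vector")
  pos <- match(target_days, fit$data$dates)
  if (anyNA(pos)) {
    miss <- target_days[is.na(pos)]
    stop("target days outside the covariate-covered span: ",
         paste(format(utils::head(miss, 5)), collapse = ", "),
         if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
  }
  observed <- !is.na(fit$data$wt[pos])
  n_draw <- nrow(fit$latent$wt)
  draws <- matrix(NA_real_, n_draw, length(pos))
  lat_col <- match(pos, fit$latent$idx_wt)
  draws[, !is.na(lat_col)] <- fit$latent$wt[, lat_col[!is.na(lat_col)], drop = FALSE]
  draws[, observed] <- matrix(rep(fit$data$wt[pos[observed]], each = n_draw),
                              nrow = n_draw)
  qs <- t(apply(draws, 2, quantile, c(0.025, 0.25, 0.5, 0.75, 0.975)))
  out <- data.frame(date = target_days, observed = observed,
                    mean = colMeans(draws), median = qs[, 3],
                    q2.5 = qs[, 1], q25 = qs[, 2], q75 = qs[, 4], q97.5 = qs[, 5],
                    row.names = NULL)
  class(out) <- c("stm_prediction", "data.frame")
  if (return_draws) attr(out, "draws") <- draws
  out
}

#' Project water-temperature warming under uniform air-temperature offsets
#'
#' For each posterior draw and each AT warming offset `delta_at`, every AT
#' window extremum shifts by `delta_at` while the discharge extrema and all
#' residual structures stay fixed. Through the window-extrema regression the
#' annual-mean WT then shifts by `(theta1 + theta1p) / 2 * delta_at` in that
#' draw (the seasonal maximum by `theta1 * delta_at` and the minimum by
#' `theta1p * delta_at`); a uniform AT shift leaves the daily deviations
#' unchanged, so the daily link contributes nothing to mean warming. The
#' function summarizes the per-offset posterior of the annual-mean WT warming
#' and, for completeness, of the seasonal extrema warming.
#'
#' @param fit an `stm_fit`.
#' @param at_offsets strictly increasing grid of AT warming offsets in degC,
#'   each within (-10, 10); default 0 to 5 by 0.5.
#' @param return_draws attach the per-draw annual warming matrix
#'   (draws x offsets) as attribute `"draws"`.
#' @return data.frame of class `stm_warming`: `offset`, `median`, `q2.5`,
#'   `q25`, `q75`, `q97.5` (annual-mean WT warming, degC), plus `max_median`
#'   and `min_median` for the seasonal extrema pathways.
#' @export
project_warming <- function(fit, at_offsets = seq(0, 5, by = 0.5),
                            return_draws = FALSE) {
  stopifnot(inherits(fit, "stm_fit"))
  if (any(!is.finite(at_offsets)) || any(at_offsets <= -10 | at_offsets >= 10)) {
    stop("AT offsets must lie within (-10, 10) degC")
  }
  if (length(at_offsets) > 1 && any(diff(at_offsets) <= 0)) {
    stop("`at_offsets` must be strictly increasing")
  }
  m <- as.matrix(fit$draws)
  slope_mean <- (m[, "theta1"] + m[, "theta1p"]) / 2
  warm <- outer(slope_mean, at_offsets)      # draws x offsets, exact per draw
  qs <- t(apply(warm, 2, quantile, c(0.025, 0.25, 0.5, 0.75, 0.975)))
  out <- data.frame(offset = at_offsets,
                    median = qs[, 3], q2.5 = qs[, 1], q25 = qs[, 2],
                    q75 = qs[, 4], q97.5 = qs[, 5],
                    max_median = apply(outer(m[, "theta1"], at_offsets), 2, median),
                    min_median = apply(outer(m[, "theta1p"], at_offsets), 2, median),
                    row.names = NULL)
  class(out) <- c("stm_warming", "data.frame")
  if (return_draws) attr(out, "draws") <- warm
  out
}
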