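#' Daily series container
#'
#' Holds one variable's dated daily values with an explicit missingness mask.
#' Water and air temperature are in degrees Celsius; discharge is stored on the
#' natural-log scale (log m3/s). Gaps are represented by `NA` values on present
#' rows, never by absent rows.
#'
#' @param dates consecutive `Date` vector.
#' @param values numeric vector, same length; `NA` marks a gap.
#' @param kind one of `"wt"`, `"at"`, `"logq"`.
#' @return an object of class `stm_series`: list with `dates`, `values`,
#'   `observed` (logical mask) and `kind`.
#' @export
daily_series <- function(dates, values, kind = c("wt", "at", "logq")) {
  kind <- match.arg(kind)
  if (length(dates) != length(values)) stop("`dates` and `values` lengths differ")
  build_windows(dates)  # validates consecutiveness/duplicates
  values <- as.numeric(values)
  observed <- !is.na(values)
  v <- values[observed]
  if (any(!is.finite(v))) stop("non-finite observed value in ", kind, " series")
  if (kind %in% c("wt", "at") && any(v <= -30 | v >= 45)) {
    stop(kind, " values outside the (-30, 45) degC sanity bounds")
  }
  structure(list(dates = dates, values = values, observed = observed, kind = kind),
            class = "stm_series")
}

#' @export
print.stm_series <- function(x, ...) {
  cat(sprintf("stm_series [%s]: %d days (%s .. %s), %.1f%% missing\n",
              x$kind, length(x$dates), format(x$dates[1]),
              format(x$dates[length(x$dates)]), 100 * mean(!x$observed)))
  invisible(x)
}

#' Assemble a model dataset from daily series
#'
#' Aligns the water-temperature series with its covariates on one common
#' consecutive daily grid (the union of the spans) and attaches the half-year
#' window index. The covariates must cover every day where WT estimates will be
#' requested; days outside a series' own span count as missing for that series.
#'
#' @param wt,at `stm_series` of kind `"wt"` and `"at"`.
#' @param q optional `stm_series` of kind `"logq"`; `NULL` for the
#'   air-temperature-only configuration.
#' @return object of class `stm_data`: list with `dates`, `windows`
#'   (see [build_windows()]), numeric vectors `wt`, `at`, `q` (NA = missing;
#'   `q` is `NULL` without discharge) and `use_discharge`.
#' @export
stm_data <- function(wt, at, q = NULL) {
  stopifnot(inherits(wt, "stm_series"), wt$kind == "wt")
  stopifnot(inherits(at, "stm_series"), at$kind == "at")
  if (!is.null(q)) stopifnot(inherits(q, "stm_series"), q$kind == "logq")
  all_series <- c(list(wt, at), if (!is.null(q)) list(q))
  lo <- min(do.call(c, lapply(all_series, function(s) s$dates[1L])))
  hi <- max(do.call(c, lapply(all_series, function(s) s$dates[length(s$dates)])))
  dates <- seq(lo, hi, by = "day")
  expand <- function(s) {
    v <- rep(NA_real_, length(dates))
    v[match(s$dates, dates)] <- s$values
    v
  }
  if (all(is.na(expand(wt)))) stop("water-temperature series has no observed values")
  structure(list(
    dates = dates,
    windows = build_windows(dates),
    wt = expand(wt), at = expand(at),
    q = if (is.null(q)) NULL else expand(q),
    use_discharge = !is.null(q)
  ), class = "stm_data")
}

#' @export
print.stm_data <- function(x, ...) {
  cat(sprintf("stm_data: %d days (%s .. %s), %d windows, discharge: %s\n",
              length(x$dates), format(x$dates[1]), format(x$dates[length(x$dates)]),
              n_windows(x$windows), if (x$use_discharge) "yes" else "no"))
  miss <- function(v) sprintf("%.2f%%", 100 * mean(is.na(v)))
  cat("  missing: wt", miss(x$wt), " at", miss(x$at),
      if (x$use_discharge) paste(" q", miss(x$q)), "\n")
  invisible(x)
}
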