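#' Read a daily input table
#'
#' Reads a CSV with columns `date` (ISO-8601), `wt`, `at` and optionally `q`
#' (discharge in m3/s). Empty cells or `NA` mark gaps. Discharge is
#' natural-log transformed at ingestion; nonpositive discharge values are
#' floored at `q_epsilon` first, with a warning. A file without a `q` column
#' yields an air-temperature-only dataset. An ingestion report (span, missing
#' percentages) is emitted as a message.
#'
#' @param path CSV file path.
#' @param q_epsilon floor (m3/s) applied to nonpositive discharge before the
#'   log transform.
#' @param quiet suppress the ingestion report.
#' @return an `stm_data` object.
#' @export
read_daily_input <- function(path, q_epsilon = 0.001, quiet = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "wt", "at")
  if (!all(need %in% names(raw))) {
    stop("input must have columns date, wt, at (and optionally q); found: ",
         paste(names(raw), collapse = ", "))
  }
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop("unparseable date(s) at row(s): ",
         paste(utils::head(which(is.na(dates)), 5), collapse = ", "))
  }
  if (anyDuplicated(dates)) {
    stop("duplicate date(s) at row(s): ",
         paste(utils::head(which(duplicated(dates)), 5), collapse = ", "))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  wt_v <- num(raw$wt); at_v <- num(raw$at)
  if (all(is.na(wt_v))) stop("water-temperature column is entirely missing")
  q_series <- NULL
  if ("q" %in% names(raw)) {
    q_v <- num(raw$q)
    bad <- which(!is.na(q_v) & q_v <= 0)
    if (length(bad)) {
      warning(length(bad), " nonpositive discharge value(s) floored at ",
              q_epsilon, " m3/s before the log transform (first at row ", bad[1], ")")
      q_v[bad] <- q_epsilon
    }
    q_series <- daily_series(dates, log(q_v), "logq")
  }
  data <- stm_data(wt = daily_series(dates, wt_v, "wt"),
                   at = daily_series(dates, at_v, "at"),
                   q = q_series)
  if (!quiet) {
    miss <- function(v) sprintf("%.2f%%", 100 * mean(is.na(v)))
    message(sprintf("read %d days (%s .. %s); missing: wt %s, at %s%s",
                    length(data$dates), format(data$dates[1]),
                    format(data$dates[length(data$dates)]),
                    miss(data$wt), miss(data$at),
                    if (data$use_discharge) paste0(", q ", miss(data$q))
                    else " (no discharge column: running without Q)"))
  }
  data
}

#' Write a dataset back to the input CSV dialect
#'
#' Inverse of [read_daily_input()]: one row per day with `date`, `wt`, `at`
#' and, when present, `q` on the original m3/s scale (`exp` of the stored
#' log values).
#'
#' @param data an `stm_data`.
#' @param path output CSV path.
#' @export
write_daily_input <- function(data, path) {
  stopifnot(inherits(data, "stm_data"))
  df <- data.frame(date = format(data$dates), wt = data$wt, at = data$at)
  if (data$use_discharge) df$q <- exp(data$q)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize posterior draws to a long table
#'
#' One row per (chain, iteration, parameter) triple, the format consumed by
#' generic MCMC post-processing tools. With `include_latent = TRUE` the latent
#' WT draws at unobserved days are appended as parameters named
#' `wt[YYYY-MM-DD]` (the file grows accordingly for gappy series).
#'
#' @param fit an `stm_fit`.
#' @param path output CSV path.
#' @param include_latent also write the latent WT draws.
#' @export
write_draws_csv <- function(fit, path, include_latent = FALSE) {
  stopifnot(inherits(fit, "stm_fit"))
  n_keep <- nrow(as.matrix(fit$draws[[1]]))
  tabs <- lapply(seq_along(fit$draws), function(ch) {
    m <- as.matrix(fit$draws[[ch]])
    if (include_latent && length(fit$latent$idx_wt)) {
      lat <- fit$latent$wt[(ch - 1L) * n_keep + seq_len(n_keep), , drop = FALSE]
      colnames(lat) <- sprintf("wt[%s]", format(fit$data$dates[fit$latent$idx_wt]))
      m <- cbind(m, lat)
    }
    data.frame(chain = ch, iteration = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  })
  write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_draws_csv
#' @export
write_convergence_csv <- function(fit, path) {
  stopifnot(inherits(fit, "stm_fit"))
  write.csv(fit$convergence, path, row.names = FALSE)
  invisible(path)
}

# truth record of a simulation as a flat (parameter, value) table
truth_table <- function(truth) {
  rows <- list()
  add <- function(name, value) rows[[length(rows) + 1]] <<- data.frame(
    parameter = name, value = value)
  flat <- function(prefix, x) {
    for (nm in names(x)) {
      v <- x[[nm]]
      if (length(v) == 1) add(paste0(prefix, nm), v)
      else if (is.numeric(v)) {
        for (i in seq_along(v)) add(sprintf("%s%s[%d]", prefix, nm, i), v[i])
      }
    }
  }
  flat("at.", truth$at)
  if (!is.null(truth$q)) flat("q.", truth$q)
  flat("wt.", truth$wt)
  flat("link.", unclass(truth$link))
  do.call(rbind, rows)
}
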