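#' Build six-month calendar windows over a run of consecutive days
#'
#' Partitions a consecutive daily date vector into calendar half-year windows
#' (Jan 1 - Jun 30 and Jul 1 - Dec 31). Each window carries the constant mean
#' `alpha` and sine amplitude `beta` of the decomposition; the sinusoid itself
#' runs on day-of-year with the year's true length (365 or 366). Partial windows
#' at the series edges are kept but flagged, so downstream summaries can exclude
#' them.
#'
#' @param dates a `Date` vector, strictly increasing and consecutive (every
#'   calendar day present; gaps in the *data* are represented by missing values,
#'   never by absent rows).
#' @return an object of class `stm_windows`: a list with
#'   \describe{
#'     \item{day}{data.frame with one row per day: `date`, `win` (integer window
#'       id), `doy` (day of year, 1-based), `n_year` (365 or 366).}
#'     \item{window}{data.frame with one row per window: `win`, `year`, `half`
#'       (1 = Jan-Jun, 2 = Jul-Dec), `start`, `end`, `n_days`, `full` (logical:
#'       covers the complete calendar half-year).}
#'   }
#' @examples
#' w <- build_windows(seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day"))
#' w$window$n_days  # 181, 184
#' @export
build_windows <- function(dates) {
  if (length(dates) == 0L) stop("`dates` must be nonempty")
  if (!inherits(dates, "Date")) stop("`dates` must be a Date vector")
  if (anyDuplicated(dates)) {
    stop("duplicated date: ", format(dates[duplicated(dates)][1L]))
  }
  d <- diff(as.integer(dates))
  if (any(d != 1L)) {
    bad <- which(d != 1L)[1L]
    stop("dates must be consecutive calendar days; gap or disorder after ",
         format(dates[bad]))
  }
  year  <- as.integer(format(dates, "%Y"))
  month <- as.integer(format(dates, "%m"))
  doy   <- as.integer(format(dates, "%j"))
  half  <- ifelse(month <= 6L, 1L, 2L)
  n_year <- ifelse(is_leap_year(year), 366L, 365L)
  key <- year * 2L + half
  win <- cumsum(c(1L, diff(key) != 0L))

  idx <- split(seq_along(dates), win)
  wdf <- do.call(rbind, lapply(idx, function(i) {
    y <- year[i[1L]]; h <- half[i[1L]]
    full_len <- half_year_length(y, h)
    data.frame(win = win[i[1L]], year = y, half = h,
               start = dates[i[1L]], end = dates[i[length(i)]],
               n_days = length(i), full = length(i) == full_len)
  }))
  rownames(wdf) <- NULL
  structure(list(
    day = data.frame(date = dates, win = win, doy = doy, n_year = n_year),
    window = wdf
  ), class = "stm_windows")
}

is_leap_year <- function(y) (y %% 4L == 0L & y %% 100L != 0L) | y %% 400L == 0L

half_year_length <- function(year, half) {
  ifelse(half == 1L, ifelse(is_leap_year(year), 182L, 181L), 184L)
}

#' @export
print.stm_windows <- function(x, ...) {
  cat("stm_windows:", nrow(x$day), "days in", nrow(x$window), "half-year windows (",
      sum(!x$window$full), "partial )\n")
  invisible(x)
}

n_windows <- function(windows) nrow(windows$window)
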