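# Annual waste formula, monthly disaggregation, and calendar-window
# allocation. All public quantities are in tonnes; the generation formula is
# evaluated in kg and divided by 1000 at the boundary.

#' Monthly series container
#'
#' A thin data.frame wrapper holding a contiguous calendar-indexed monthly
#' series (visits or tonnes of waste). Months must be contiguous and unique;
#' values must be nonnegative.
#'
#' @param year integer vector of calendar years.
#' @param month integer vector of months (1-12), same length as `year`.
#' @param value numeric vector of nonnegative values.
#' @return A data.frame of class `mw_monthly` with columns `year`, `month`,
#'   `value`.
#' @examples
#' monthly_series(2019, 1:12, rep(100, 12))
#' @export
monthly_series <- function(year, month, value) {
  n <- max(length(year), length(month), length(value))
  df <- data.frame(year = as.integer(rep_len(year, n)),
                   month = as.integer(rep_len(month, n)),
                   value = as.numeric(rep_len(value, n)))
  if (any(df$month < 1L | df$month > 12L)) {
    stop("months must be in 1..12", call. = FALSE)
  }
  idx <- df$year * 12L + (df$month - 1L)
  if (n > 1L && !all(diff(idx) == 1L)) {
    stop("months must be contiguous and unique", call. = FALSE)
  }
  if (any(!is.finite(df$value)) || any(df$value < 0)) {
    stop("values must be finite and >= 0", call. = FALSE)
  }
  class(df) <- c("mw_monthly", "data.frame")
  df
}

as_monthly_series <- function(x) {
  if (inherits(x, "mw_monthly")) return(x)
  if (is.data.frame(x) && all(c("year", "month", "value") %in% names(x))) {
    return(monthly_series(x$year, x$month, x$value))
  }
  stop("expected a monthly series (columns year, month, value)", call. = FALSE)
}

#' Inclusive calendar date window
#'
#' @param start,end `Date` (or coercible strings), inclusive on both ends.
#' @return list of class `mw_window` with `start` and `end`.
#' @examples
#' date_window("2020-01-23", "2020-04-28")
#' @export
date_window <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("invalid dates", call. = FALSE)
  if (start > end) stop("window start must not be after end", call. = FALSE)
  structure(list(start = start, end = end), class = "mw_window")
}

days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  nxt <- seq(first, by = "1 month", length.out = 2L)[2L]
  as.integer(nxt - first)
}

#' Annual medical waste generation (empirical formula)
#'
#' Evaluates the empirical generation formula
#' \eqn{Q = 365 \cdot B \cdot P \cdot M + N \cdot S} (kg/year) and converts
#' to tonnes. The first term is inpatient waste (occupied bed-days times a
#' per-bed daily rate), the second outpatient waste (visits times a
#' per-visit rate). 365 is used for the year length regardless of leap years.
#'
#' @param beds number of beds in all medical institutions (absolute count).
#' @param utilization bed-utilization rate as a fraction; values slightly
#'   above 1 (up to 1.2) are allowed, as over-occupancy occurs in practice.
#' @param visits annual visit count (absolute count).
#' @param m waste generation rate in kg per occupied bed per day
#'   (default 0.5).
#' @param s waste generation rate in kg per visit (default 0.04).
#' @return Annual waste in tonnes (vectorised over the inputs).
#' @examples
#' # Hubei 2019: 403,300 beds at 92.3% utilization, 354 million visits
#' annual_waste(403300, 0.923, 3.54e8)
#' @export
annual_waste <- function(beds, utilization, visits, m = 0.5, s = 0.04) {
  if (any(beds <= 0) || any(visits < 0)) {
    stop("beds must be > 0 and visits >= 0", call. = FALSE)
  }
  if (any(utilization <= 0) || any(utilization > 1.2)) {
    stop("utilization must be in (0, 1.2]", call. = FALSE)
  }
  # zero rates are allowed so each term of the formula can be isolated
  if (any(m < 0) || any(s < 0)) stop("m and s must be >= 0", call. = FALSE)
  (365 * beds * utilization * m + visits * s) / 1000
}

#' Monthly weights from a visit series
#'
#' Computes the share of a year's visits falling in each calendar month,
#' \eqn{\omega_i = n_i / \sum_{i=1}^{12} n_i}. These shares disaggregate an
#' annual waste total into months, on the assumption that monthly waste is
#' proportional to monthly visits.
#'
#' @param visits a monthly series (see [monthly_series()]) covering exactly
#'   the 12 months of one calendar year.
#' @return list of class `mw_weights` with `year` and `w` (12 fractions
#'   summing to 1). Individual zero months are allowed; a zero annual total
#'   is an error.
#' @export
month_weights <- function(visits) {
  visits <- as_monthly_series(visits)
  if (nrow(visits) != 12L || length(unique(visits$year)) != 1L ||
      !identical(sort(visits$month), 1:12)) {
    stop("need exactly the 12 months of one calendar year", call. = FALSE)
  }
  tot <- sum(visits$value)
  if (tot <= 0) stop("annual visit total must be > 0", call. = FALSE)
  w <- visits$value[order(visits$month)] / tot
  structure(list(year = visits$year[1L], w = w), class = "mw_weights")
}

#' Disaggregate an annual total into a monthly series
#'
#' \eqn{q_i = Q \cdot \omega_i}: the annual total is split across months in
#' proportion to the weights, so the 12 values sum to `Q` exactly (up to
#' floating point).
#'
#' @param q annual total (tonnes), `q >= 0`.
#' @param weights an `mw_weights` object from [month_weights()], or a bare
#'   numeric 12-vector of shares summing to 1 plus a `year`.
#' @param year calendar year, required when `weights` is a bare vector.
#' @return An `mw_monthly` series of 12 tonnes values.
#' @export
monthly_waste <- function(q, weights, year = NULL) {
  if (q < 0) stop("annual total must be >= 0", call. = FALSE)
  if (inherits(weights, "mw_weights")) {
    year <- weights$year
    w <- weights$w
  } else {
    w <- as.numeric(weights)
    if (is.null(year)) stop("year required with bare weights", call. = FALSE)
  }
  if (length(w) != 12L || abs(sum(w) - 1) > 1e-12) {
    stop("weights must be 12 shares summing to 1", call. = FALSE)
  }
  monthly_series(year, 1:12, q * w)
}

#' Allocate a monthly series across a date window pro rata by days
#'
#' Assumes production is constant within each calendar month: each month
#' overlapping the (inclusive) window contributes
#' `value * overlap_days / days_in_month`, with true calendar day counts
#' (February 2020 has 29 days). A window spanning exactly one full month
#' returns that month's value unchanged.
#'
#' @param series an `mw_monthly` series covering the window.
#' @param window an [date_window()].
#' @return data.frame with one row per overlapped month: `year`, `month`,
#'   `overlap_days`, `month_days`, `month_value`, `allocated`, plus
#'   attribute `total` (full-precision sum).
#' @export
allocate_window <- function(series, window) {
  series <- as_monthly_series(series)
  if (!inherits(window, "mw_window")) stop("window must be a date_window", call. = FALSE)
  first <- as.Date(sprintf("%d-%02d-01", series$year[1L], series$month[1L]))
  nlast <- nrow(series)
  last_start <- as.Date(sprintf("%d-%02d-01", series$year[nlast], series$month[nlast]))
  last_end <- last_start + days_in_month(series$year[nlast], series$month[nlast]) - 1L
  if (window$start < first || window$end > last_end) {
    stop("window extends outside the series coverage", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(series)), function(i) {
    y <- series$year[i]; mo <- series$month[i]
    ms <- as.Date(sprintf("%d-%02d-01", y, mo))
    nd <- days_in_month(y, mo)
    me <- ms + nd - 1L
    ov <- as.integer(min(window$end, me) - max(window$start, ms)) + 1L
    if (ov <= 0L) return(NULL)
    data.frame(year = y, month = mo, overlap_days = ov, month_days = nd,
               month_value = series$value[i],
               allocated = series$value[i] * ov / nd)
  })
  out <- do.call(rbind, rows)
  attr(out, "total") <- sum(out$allocated)
  out
}
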