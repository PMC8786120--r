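# CSV readers/writers for institution panels and monthly series, plus the
# published Hubei reference inputs used by the replay pipeline.

#' Read an institution panel from CSV
#'
#' Two dialects are supported. `"absolute"` expects columns
#' `year,beds,utilization,visits` in absolute counts with utilization as a
#' fraction. `"statistical"` expects the yearbook-style columns
#' `year,beds_10k,utilization_pct,visits_1e8` — beds in units of 10^4,
#' utilization in percent, and annual visits in units of 10^8 (the Chinese
#' yi, often mislabelled "billion" in translated tables) — and converts them
#' to absolute counts on read.
#'
#' @param path CSV file path.
#' @param dialect `"absolute"` or `"statistical"`.
#' @return data.frame with columns `year`, `beds`, `utilization`, `visits`
#'   (absolute units).
#' @export
read_institution_panel <- function(path, dialect = c("absolute", "statistical")) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "statistical") {
    need <- c("year", "beds_10k", "utilization_pct", "visits_1e8")
    if (!all(need %in% names(df))) {
      stop("statistical dialect needs columns ", paste(need, collapse = ","), call. = FALSE)
    }
    df <- data.frame(year = as.integer(df$year),
                     beds = df$beds_10k * 1e4,
                     utilization = df$utilization_pct / 100,
                     visits = df$visits_1e8 * 1e8)
  } else {
    need <- c("year", "beds", "utilization", "visits")
    if (!all(need %in% names(df))) {
      stop("absolute dialect needs columns ", paste(need, collapse = ","), call. = FALSE)
    }
    df <- df[need]
  }
  validate_panel(df)
  df
}

validate_panel <- function(df) {
  if (any(df$beds <= 0) || any(df$visits <= 0)) {
    stop("panel beds and visits must be > 0", call. = FALSE)
  }
  if (any(df$utilization <= 0) || any(df$utilization > 1.2)) {
    stop("panel utilization must be in (0, 1.2]", call. = FALSE)
  }
  invisible(df)
}

#' Write an institution panel to CSV (absolute dialect)
#' @param panel data.frame with `year`, `beds`, `utilization`, `visits`.
#' @param path output path.
#' @export
write_institution_panel <- function(panel, path) {
  utils::write.csv(panel[c("year", "beds", "utilization", "visits")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a monthly series CSV (`year,month,value`)
#' @param path CSV path.
#' @return [read_monthly_series()] returns an `mw_monthly` series.
#' @export
read_monthly_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_monthly_series(df)
}

#' @rdname read_monthly_series
#' @param series an `mw_monthly` series.
#' @export
write_monthly_series <- function(series, path) {
  series <- as_monthly_series(series)
  utils::write.csv(as.data.frame(series), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published Hubei reference inputs
#'
#' Bundles the public statistics the Hubei analysis consumes: the annual
#' institution panel 2008-2019 (National Bureau of Statistics of China:
#' beds in 10^4, utilization in percent, visits in 10^8), the four published
#' counterfactual monthly forecasts for January-April 2020 (tonnes), the
#' epidemic window 2020-01-23 to 2020-04-28, and the officially reported
#' 24,357.99 t of medical waste disposed over that window.
#'
#' @return list with `panel` (absolute units), `forecasts_2020`
#'   (`mw_monthly`, Jan-Apr 2020), `window` (`mw_window`),
#'   `actual_disposed` (tonnes), and the headline rates `m` (kg/bed/day)
#'   and `s` (kg/visit).
#' @examples
#' ref <- hubei_reference()
#' annual_waste(ref$panel$beds, ref$panel$utilization, ref$panel$visits)
#' @export
hubei_reference <- function() {
  panel <- data.frame(
    year = 2008:2019,
    beds = c(16.73, 18.72, 20.04, 22.40, 25.30, 28.82,
             31.75, 34.31, 36.06, 37.62, 39.35, 40.33) * 1e4,
    utilization = c(87.3, 92.7, 96.1, 98.7, 99.3, 96.5,
                    96.1, 92.4, 92.0, 92.7, 92.7, 92.3) / 100,
    visits = c(1.44, 2.18, 2.39, 2.68, 3.06, 3.21,
               3.45, 3.48, 3.55, 3.56, 3.51, 3.54) * 1e8
  )
  list(
    panel = panel,
    forecasts_2020 = monthly_series(2020, 1:4, c(6765, 5838, 6864, 6777)),
    window = date_window("2020-01-23", "2020-04-28"),
    actual_disposed = 24357.99,
    m = 0.5,
    s = 0.04
  )
}
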