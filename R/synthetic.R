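# Synthetic-data generators: institution panels, seasonal monthly visit
# series, and shocked disposal totals. These emulate the statistical
# structure of the real inputs (growing capacity, February trough / March
# peak seasonality, an epidemic excess over a window) so the full pipeline
# can be exercised and tested with known ground truth. Noise is
# multiplicative lognormal with unit mean, keeping counts strictly positive.

#' Seasonality profile: monthly shares of annual visits
#'
#' @param shares numeric 12-vector of strictly positive shares summing to 1
#'   (within 1e-12).
#' @return numeric 12-vector of class `mw_season`.
#' @export
seasonality_profile <- function(shares) {
  shares <- as.numeric(shares)
  if (length(shares) != 12L) stop("need 12 monthly shares", call. = FALSE)
  if (any(shares <= 0)) stop("all shares must be > 0", call. = FALSE)
  if (abs(sum(shares) - 1) > 1e-12) stop("shares must sum to 1", call. = FALSE)
  structure(shares, class = "mw_season")
}

#' Default synthetic seasonality profile
#'
#' A stylised monthly-visit profile with a February minimum (spring-festival
#' lull), a March maximum (post-festival rebound) and mildly elevated
#' May-August (tourist season) — the qualitative seasonal shape of hospital
#' visits in Hubei. The underlying real monthly counts are not published;
#' these shares are synthetic and carry no empirical weight beyond their
#' ordering.
#'
#' @return An `mw_season` profile.
#' @export
default_seasonality <- function() {
  raw <- c(jan = 0.95, feb = 0.72, mar = 1.18, apr = 1.02,
           may = 1.08, jun = 1.07, jul = 1.09, aug = 1.08,
           sep = 1.00, oct = 0.98, nov = 0.92, dec = 0.91)
  seasonality_profile(raw / sum(raw))
}

#' Panel generator configuration
#'
#' Defaults describe a Hubei-like six-year system (2014-2019): initial
#' capacity and utilization matching the 2014 yearbook row, with the
#' geometric bed/visit growth and linear utilization drift implied by the
#' 2014-2019 rows.
#'
#' @param start_year first calendar year.
#' @param n_years number of years.
#' @param beds0 bed count in the first year.
#' @param bed_growth geometric growth rate of beds per year.
#' @param util0 bed utilization fraction in the first year.
#' @param util_drift additive change in utilization per year.
#' @param visits0 annual visits in the first year.
#' @param visit_growth geometric growth rate of visits per year.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise applied to beds and visits (0 = deterministic).
#' @param seed integer seed; one top-level seed fans out to independent
#'   per-generator streams.
#' @return list of class `mw_panel_cfg`.
#' @export
panel_config <- function(start_year = 2014, n_years = 6,
                         beds0 = 317500, bed_growth = 0.049,
                         util0 = 0.961, util_drift = -0.0076,
                         visits0 = 3.45e8, visit_growth = 0.0052,
                         noise_cv = 0, seed = 1L) {
  u_end <- util0 + n_years * util_drift
  if (util0 <= 0 || util0 > 1.2 || u_end <= 0 || u_end > 1.2) {
    stop("utilization path must stay in (0, 1.2]", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (n_years < 1 || beds0 <= 0 || visits0 <= 0) {
    stop("need n_years >= 1 and positive beds0/visits0", call. = FALSE)
  }
  structure(list(start_year = as.integer(start_year), n_years = as.integer(n_years),
                 beds0 = beds0, bed_growth = bed_growth,
                 util0 = util0, util_drift = util_drift,
                 visits0 = visits0, visit_growth = visit_growth,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "mw_panel_cfg")
}

# Derive a substream seed from a top-level seed and a stream label, so each
# generator draws from its own stream and adding a generator does not
# perturb the others. Kept below 2^31.
fanout_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Unit-mean lognormal multipliers with coefficient of variation cv.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic institution panel
#'
#' Beds and visits follow geometric growth with multiplicative lognormal
#' noise; utilization follows a linear drift (clamped to (0, 1.2]). With
#' `noise_cv = 0` the trajectories are exact. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg an [panel_config()] object.
#' @return data.frame with columns `year`, `beds`, `utilization`, `visits`.
#' @export
gen_institution_panel <- function(cfg) {
  stopifnot(inherits(cfg, "mw_panel_cfg"))
  k <- seq_len(cfg$n_years) - 1L
  beds <- cfg$beds0 * (1 + cfg$bed_growth)^k
  visits <- cfg$visits0 * (1 + cfg$visit_growth)^k
  util <- cfg$util0 + cfg$util_drift * k
  with_seed(fanout_seed(cfg$seed, "panel-beds"), {
    beds <- beds * lognormal_noise(cfg$n_years, cfg$noise_cv)
  })
  with_seed(fanout_seed(cfg$seed, "panel-visits"), {
    visits <- visits * lognormal_noise(cfg$n_years, cfg$noise_cv)
  })
  util <- pmin(pmax(util, 1e-6), 1.2)
  data.frame(year = cfg$start_year + k, beds = beds,
             utilization = util, visits = visits)
}

#' Generate one year of monthly visits from an annual total
#'
#' Splits `annual_visits` across months by the seasonality profile, then
#' applies independent unit-mean lognormal noise with coefficient of
#' variation `noise_cv` per month. With `noise_cv = 0` the monthly shares
#' equal the profile exactly and the months sum to `annual_visits`.
#'
#' @param annual_visits positive annual visit count.
#' @param profile an [seasonality_profile()].
#' @param noise_cv per-month noise CV (>= 0).
#' @param seed integer seed.
#' @param year calendar year stamped on the series.
#' @return An `mw_monthly` series of 12 visit counts.
#' @export
gen_monthly_visits <- function(annual_visits, profile = default_seasonality(),
                               noise_cv = 0, seed = 1L, year = 2019L) {
  if (annual_visits <= 0) stop("annual_visits must be > 0", call. = FALSE)
  if (!inherits(profile, "mw_season")) profile <- seasonality_profile(profile)
  base <- annual_visits * unclass(profile)
  vals <- with_seed(fanout_seed(seed, "monthly-visits"),
                    base * lognormal_noise(12L, noise_cv))
  monthly_series(year, 1:12, vals)
}

#' Construct a shocked epidemic-window disposal total
#'
#' Returns `counterfactual_tonnes * (1 + shock)`: the disposal total an
#' epidemic with a known relative excess `shock` would produce over a
#' window whose no-epidemic total is `counterfactual_tonnes`. Used to build
#' recovery tests with known ground truth.
#'
#' @param counterfactual_tonnes no-epidemic window total (tonnes).
#' @param shock relative excess, `shock >= -1`.
#' @return tonnes.
#' @export
gen_pandemic_disposal <- function(counterfactual_tonnes, shock) {
  if (shock < -1) stop("shock must be >= -1", call. = FALSE)
  counterfactual_tonnes * (1 + shock)
}

#' Simulate a multi-year monthly waste history
#'
#' Composes the generators with the estimation stage: generates a panel,
#' per-year monthly visit series (independent noise streams per year),
#' converts each year's annual waste (via [annual_waste()]) into a monthly
#' series using that year's visit weights, and concatenates.
#'
#' @param cfg an [panel_config()].
#' @param profile seasonality profile for visits.
#' @param m,s waste generation rates (kg/bed/day, kg/visit).
#' @return list with `panel`, `visits` (`mw_monthly`, all years) and
#'   `waste` (`mw_monthly`, all years, tonnes).
#' @export
simulate_history <- function(cfg, profile = default_seasonality(),
                             m = 0.5, s = 0.04) {
  panel <- gen_institution_panel(cfg)
  visits_l <- lapply(seq_len(nrow(panel)), function(i) {
    gen_monthly_visits(panel$visits[i], profile, cfg$noise_cv,
                       seed = fanout_seed(cfg$seed, paste0("visits-year-", i)),
                       year = panel$year[i])
  })
  waste_l <- lapply(seq_len(nrow(panel)), function(i) {
    q <- annual_waste(panel$beds[i], panel$utilization[i], panel$visits[i], m, s)
    monthly_waste(q, month_weights(visits_l[[i]]))
  })
  cat_series <- function(lst) {
    df <- do.call(rbind, lapply(lst, as.data.frame))
    monthly_series(df$year, df$month, df$value)
  }
  list(panel = panel, visits = cat_series(visits_l), waste = cat_series(waste_l))
}
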