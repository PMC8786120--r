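# Shared builders for tests. All fixtures are generated in code.

# a tiny two-pollutant emission factor table
toy_ef <- function() {
  as_emission_factors(data.frame(
    technology = c("incineration", "steam", "incineration", "steam"),
    pollutant = c("so2", "so2", "flat", "flat"),
    compartment = c("air", "air", "air", "air"),
    kg_per_tonne = c(1.0, 0.2, 0.7, 0.7)
  ))
}

# a random emission factor table for property tests
random_ef <- function(n_pollutants = 4) {
  pol <- paste0("p", seq_len(n_pollutants))
  comp <- sample(c("air", "wastewater", "residue"), n_pollutants, replace = TRUE)
  as_emission_factors(data.frame(
    technology = rep(c("incineration", "steam"), each = n_pollutants),
    pollutant = rep(pol, 2),
    compartment = rep(comp, 2),
    kg_per_tonne = round(stats::runif(2 * n_pollutants, 0, 5), 3)
  ))
}

# noiseless Hubei-like trending seasonal monthly series (6 years)
trending_seasonal <- function(q0 = 70000, growth = 0.03, years = 6) {
  prof <- unclass(default_seasonality())
  as.vector(outer(prof, q0 * (1 + growth)^(0:(years - 1))))
}

# a light forecaster config for determinism/structure tests (not accuracy)
quick_cfg <- function(seed, ...) {
  forecast_config(seed = seed, epochs = 120L, restarts = 2L, topk = 1L, ...)
}

# per-day brute-force oracle for window allocation
allocate_by_day <- function(series, window) {
  days <- seq(window$start, window$end, by = "1 day")
  sum(vapply(days, function(d) {
    y <- as.integer(format(d, "%Y")); mo <- as.integer(format(d, "%m"))
    i <- which(series$year == y & series$month == mo)
    series$value[i] / medwaste:::days_in_month(y, mo)
  }, numeric(1)))
}
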