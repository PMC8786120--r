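# Four-scenario disposal-mix emission assessment. A scenario is a convex
# split of the waste between two technology classes — high-temperature
# incineration/pyrolysis and autoclave steam sterilization — and emissions
# are emission-factor linear in the treated tonnage:
#   mass(pollutant, compartment) =
#     tonnage * (mix_incin * EF_incin + mix_steam * EF_steam).

MW_TECHNOLOGIES <- c("incineration", "steam")
MW_COMPARTMENTS <- c("air", "wastewater", "residue")

#' Disposal technology mix
#'
#' @param incineration,steam fractions in \[0, 1\] summing to 1 (within
#'   1e-12). "Incineration" covers both high-temperature incineration and
#'   pyrolysis, which the scenario definitions treat as one class.
#' @return list of class `mw_mix`.
#' @export
disposal_mix <- function(incineration, steam) {
  if (incineration < 0 || incineration > 1 || steam < 0 || steam > 1 ||
      abs(incineration + steam - 1) > 1e-12) {
    stop("mix fractions must lie in [0,1] and sum to 1", call. = FALSE)
  }
  structure(list(incineration = incineration, steam = steam), class = "mw_mix")
}

#' Named disposal scenarios
#'
#' The four standard scenarios: `BAU` (business as usual, the licensed
#' 61% incineration / 39% autoclave split), `CP` (complete pyrolysis,
#' 100/0), `MP` (more pyrolysis, 80/20) and `MS` (more steam sterilization,
#' 40/60).
#'
#' @param name one of `"BAU"`, `"CP"`, `"MP"`, `"MS"`.
#' @return An [disposal_mix()].
#' @examples
#' scenario_mix("BAU")$incineration  # 0.61
#' @export
scenario_mix <- function(name) {
  switch(toupper(name),
         BAU = disposal_mix(0.61, 0.39),
         CP  = disposal_mix(1.0, 0.0),
         MP  = disposal_mix(0.8, 0.2),
         MS  = disposal_mix(0.4, 0.6),
         stop("unknown scenario: ", name, call. = FALSE))
}

#' Emission factor tables
#'
#' An emission factor table is a data.frame with columns `technology`
#' (`incineration` or `steam`), `pollutant`, `compartment` (`air`,
#' `wastewater` or `residue`) and `kg_per_tonne` (>= 0): kg of pollutant
#' released to the compartment per tonne of waste treated by the
#' technology. Each (technology, pollutant, compartment) key must be
#' unique; a (pollutant, compartment) listed for only one technology gets
#' factor 0 for the other by explicit rule.
#'
#' `read_emission_factors()` reads and validates such a CSV and completes
#' missing-technology rows with zeros.
#'
#' @param path CSV path.
#' @return validated emission factor data.frame, class `mw_ef`.
#' @export
read_emission_factors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_emission_factors(df)
}

#' @rdname read_emission_factors
#' @param df a data.frame with the four columns above.
#' @export
as_emission_factors <- function(df) {
  need <- c("technology", "pollutant", "compartment", "kg_per_tonne")
  if (!is.data.frame(df) || !all(need %in% names(df))) {
    stop("emission factor table needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  df <- df[need]
  if (!all(df$technology %in% MW_TECHNOLOGIES)) {
    stop("technology must be one of: ", paste(MW_TECHNOLOGIES, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$compartment %in% MW_COMPARTMENTS)) {
    stop("compartment must be one of: ", paste(MW_COMPARTMENTS, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$kg_per_tonne)) || any(df$kg_per_tonne < 0)) {
    stop("factors must be finite and >= 0", call. = FALSE)
  }
  key <- paste(df$technology, df$pollutant, df$compartment, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (technology, pollutant, compartment) rows", call. = FALSE)
  }
  # complete the missing technology with factor 0
  species <- unique(df[c("pollutant", "compartment")])
  full <- merge(merge(species, data.frame(technology = MW_TECHNOLOGIES)),
                df, all.x = TRUE)
  full$kg_per_tonne[is.na(full$kg_per_tonne)] <- 0
  full <- full[order(full$compartment, full$pollutant, full$technology), ]
  rownames(full) <- NULL
  class(full) <- c("mw_ef", "data.frame")
  full
}

#' Bundled synthetic emission factor table
#'
#' Loads the emission factor fixture shipped with the package
#' (`inst/extdata/emission_factors_synthetic.csv`). These factors are
#' synthetic: the literature values the real analysis used are not
#' reproduced here. The fixture only preserves the qualitative structure of
#' the technologies — steam sterilization dominates wastewater and residue
#' releases, incineration dominates most exhaust gases (hydrogen chloride
#' the largest gas factor, nickel the largest and lead the smallest metal),
#' chloride is the largest residue species, and a few air species (ammonia,
#' mercury, phenol, chromium) are larger for steam.
#'
#' @return An `mw_ef` emission factor table.
#' @export
synthetic_emission_factors <- function() {
  read_emission_factors(system.file("extdata", "emission_factors_synthetic.csv",
                                    package = "medwaste", mustWork = TRUE))
}

#' Emissions of treating a tonnage under a disposal mix
#'
#' For every (pollutant, compartment) in the factor table,
#' `mass_kg = tonnage * (mix$incineration * EF_incin + mix$steam * EF_steam)`.
#' Linear in tonnage and affine in the incineration fraction.
#'
#' @param tonnage tonnes treated (>= 0).
#' @param mix an [disposal_mix()] or scenario name string.
#' @param ef an `mw_ef` emission factor table.
#' @param scenario optional scenario label stored on the result.
#' @return list of class `mw_emissions`: `scenario`, `tonnage`, `masses`
#'   (data.frame `pollutant`, `compartment`, `mass_kg`) and
#'   `compartment_totals` (named vector, kg).
#' @export
assess_emissions <- function(tonnage, mix, ef, scenario = NULL) {
  if (tonnage < 0) stop("tonnage must be >= 0", call. = FALSE)
  if (is.character(mix)) {
    if (is.null(scenario)) scenario <- toupper(mix)
    mix <- scenario_mix(mix)
  }
  stopifnot(inherits(mix, "mw_mix"))
  ef <- if (inherits(ef, "mw_ef")) ef else as_emission_factors(ef)
  wide <- stats::reshape(as.data.frame(ef), idvar = c("pollutant", "compartment"),
                         timevar = "technology", direction = "wide")
  names(wide) <- sub("^kg_per_tonne\\.", "", names(wide))
  masses <- data.frame(pollutant = wide$pollutant,
                       compartment = wide$compartment,
                       mass_kg = tonnage * (mix$incineration * wide$incineration +
                                            mix$steam * wide$steam))
  totals <- tapply(masses$mass_kg, masses$compartment, sum)
  structure(list(scenario = scenario, tonnage = tonnage, mix = mix,
                 masses = masses, compartment_totals = c(totals)),
            class = "mw_emissions")
}

#' Relative emission change of each scenario versus BAU
#'
#' `100 * (scenario - BAU) / BAU` per (pollutant, compartment). Cells whose
#' BAU mass is 0 are flagged `NA` with a warning and excluded from the
#' comparison.
#'
#' @param results named list of `mw_emissions`, containing `BAU`.
#' @return data.frame: `pollutant`, `compartment`, one `pct_vs_bau_<name>`
#'   column per non-BAU scenario.
#' @export
relative_change_vs_bau <- function(results) {
  if (!"BAU" %in% names(results)) stop("results must contain BAU", call. = FALSE)
  bau <- results[["BAU"]]$masses
  out <- bau[c("pollutant", "compartment")]
  zero <- bau$mass_kg == 0
  if (any(zero)) warning("BAU mass is 0 for some pollutants; flagged NA")
  for (nm in setdiff(names(results), "BAU")) {
    m <- results[[nm]]$masses
    stopifnot(identical(m$pollutant, bau$pollutant))
    pct <- 100 * (m$mass_kg - bau$mass_kg) / bau$mass_kg
    pct[zero] <- NA_real_
    out[[paste0("pct_vs_bau_", nm)]] <- pct
  }
  out
}

#' Order scenarios by emitted mass of one species
#'
#' Sorts the assessed scenarios by the mass of a (pollutant, compartment)
#' cell, descending. Because emissions are affine in the incineration
#' fraction, the order is exactly CP > MP > BAU > MS when the incineration
#' factor exceeds the steam factor, and the reverse otherwise; ties (equal
#' factors) are reported as ties, not silently broken.
#'
#' @param results named list of `mw_emissions` (all four scenarios).
#' @param pollutant,compartment the species to rank.
#' @return data.frame `scenario`, `mass_kg`, `rank` (min-rank with ties),
#'   with attribute `ordering` — a string such as `"CP>MP>BAU>MS"` using
#'   `=` for ties.
#' @export
ordering_check <- function(results, pollutant, compartment) {
  mass <- vapply(results, function(r) {
    i <- r$masses$pollutant == pollutant & r$masses$compartment == compartment
    if (!any(i)) stop("species not found: ", pollutant, "/", compartment,
                      call. = FALSE)
    r$masses$mass_kg[i]
  }, numeric(1))
  ord <- order(-mass)
  out <- data.frame(scenario = names(mass)[ord], mass_kg = mass[ord],
                    rank = rank(-mass, ties.method = "min")[ord])
  sep <- ifelse(diff(out$mass_kg) == 0, "=", ">")
  attr(out, "ordering") <- paste0(out$scenario,
                                  c(sep, ""), collapse = "")
  rownames(out) <- NULL
  out
}
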