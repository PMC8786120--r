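test_that("the four scenario mixes carry the stated technology splits", {
  expect_equal(scenario_mix("BAU")$incineration, 0.61)
  expect_equal(scenario_mix("BAU")$steam, 0.39)
  expect_equal(scenario_mix("CP")$steam, 0)
  expect_equal(scenario_mix("MP")$incineration, 0.8)
  expect_equal(scenario_mix("MS")$steam, 0.6)
  expect_error(scenario_mix("XX"), "unknown")
  expect_error(disposal_mix(0.7, 0.4), "sum to 1")
  expect_error(disposal_mix(-0.1, 1.1), "sum to 1|\\[0,1\\]")
})

test_that("emissions are the tonnage-weighted convex mix of the factors", {
  ef <- toy_ef()
  # BAU on the worked toy factor: 100 * (0.61*1.0 + 0.39*0.2) = 68.8 kg
  bau <- assess_emissions(100, "BAU", ef)
  expect_equal(bau$masses$mass_kg[bau$masses$pollutant == "so2"], 68.8)
  # zero tonnage: all zero
  z <- assess_emissions(0, "MS", ef)
  expect_true(all(z$masses$mass_kg == 0))
  # pure technology: exactly tonnage x incineration factor
  cp <- assess_emissions(100, "CP", ef)
  expect_equal(cp$masses$mass_kg[cp$masses$pollutant == "so2"], 100)
  # linear in tonnage
  half <- assess_emissions(50, "BAU", ef)
  expect_equal(2 * half$masses$mass_kg, bau$masses$mass_kg)
  expect_error(assess_emissions(-1, "BAU", ef), ">= 0")
})

test_that("compartment totals conserve the per-pollutant masses", {
  set.seed(501)
  for (k in 1:10) {
    ef <- random_ef(6)
    res <- assess_emissions(stats::runif(1, 10, 1e4), "MP", ef)
    tot <- tapply(res$masses$mass_kg, res$masses$compartment, sum)
    expect_equal(res$compartment_totals[names(tot)], c(tot))
  }
})

test_that("relative change versus business-as-usual matches hand arithmetic", {
  ef <- toy_ef()
  res <- lapply(stats::setNames(nm = c("BAU", "CP", "MP", "MS")),
                function(nm) assess_emissions(100, nm, ef))
  rc <- relative_change_vs_bau(res)
  ms_so2 <- rc$pct_vs_bau_MS[rc$pollutant == "so2"]
  expect_equal(ms_so2, 100 * ((0.4 * 1 + 0.6 * 0.2) - 0.688) / 0.688)
  expect_equal(ms_so2, -24.4186, tolerance = 1e-4)
  # equal factors in both technologies: invariant to the mix
  expect_true(all(abs(rc[rc$pollutant == "flat",
                         grep("pct", names(rc))]) < 1e-12))
  # zero BAU mass is flagged, not divided by
  ef0 <- as_emission_factors(data.frame(
    technology = c("incineration", "steam"), pollutant = "x",
    compartment = "air", kg_per_tonne = c(0, 0)))
  res0 <- lapply(stats::setNames(nm = c("BAU", "MS")),
                 function(nm) assess_emissions(100, nm, ef0))
  expect_warning(rc0 <- relative_change_vs_bau(res0), "0")
  expect_true(is.na(rc0$pct_vs_bau_MS))
})

test_that("scenario ordering follows the sign of the factor difference", {
  ef <- synthetic_emission_factors()
  res <- lapply(stats::setNames(nm = c("BAU", "CP", "MP", "MS")),
                function(nm) assess_emissions(3366.99, nm, ef))
  # steam-dominant species: more steam means more release
  expect_equal(attr(ordering_check(res, "chloride", "wastewater"), "ordering"),
               "MS>BAU>MP>CP")
  expect_equal(attr(ordering_check(res, "chloride", "residue"), "ordering"),
               "MS>BAU>MP>CP")
  # incineration-dominant gas: more pyrolysis means more release
  expect_equal(attr(ordering_check(res, "hydrogen_chloride", "air"), "ordering"),
               "CP>MP>BAU>MS")
  expect_equal(attr(ordering_check(res, "nitrogen_oxides", "air"), "ordering"),
               "CP>MP>BAU>MS")
  expect_error(ordering_check(res, "nope", "air"), "not found")
})

test_that("ties are reported as ties", {
  res <- lapply(stats::setNames(nm = c("BAU", "CP", "MP", "MS")),
                function(nm) assess_emissions(100, nm, toy_ef()))
  oc <- ordering_check(res, "flat", "air")
  expect_equal(oc$rank, rep(1L, 4))
  expect_match(attr(oc, "ordering"), "=")
})

test_that("emissions are affine in the incineration fraction", {
  set.seed(502)
  grid <- seq(0, 1, by = 0.1)
  for (k in 1:20) {
    ef <- random_ef(3)
    tonnes <- stats::runif(1, 1, 5000)
    wide <- stats::reshape(as.data.frame(ef),
                           idvar = c("pollutant", "compartment"),
                           timevar = "technology", direction = "wide")
    for (i in seq_len(nrow(wide))) {
      # brute-force evaluation at 11 grid points vs the affine form
      brute <- vapply(grid, function(a) {
        r <- assess_emissions(tonnes, disposal_mix(a, 1 - a), ef)
        r$masses$mass_kg[r$masses$pollutant == wide$pollutant[i] &
                           r$masses$compartment == wide$compartment[i]]
      }, numeric(1))
      slope <- wide$kg_per_tonne.incineration[i] - wide$kg_per_tonne.steam[i]
      affine <- tonnes * (wide$kg_per_tonne.steam[i] + slope * grid)
      expect_equal(brute, affine, tolerance = 1e-12)
    }
  }
})

test_that("orderings over random factor tables obey the sign rule", {
  set.seed(503)
  mixes <- c(BAU = 0.61, CP = 1.0, MP = 0.8, MS = 0.4)
  for (k in 1:20) {
    ef <- random_ef(4)
    res <- lapply(stats::setNames(nm = names(mixes)), function(nm)
      assess_emissions(1000, disposal_mix(mixes[[nm]], 1 - mixes[[nm]]), ef))
    wide <- stats::reshape(as.data.frame(ef),
                           idvar = c("pollutant", "compartment"),
                           timevar = "technology", direction = "wide")
    for (i in seq_len(nrow(wide))) {
      oc <- ordering_check(res, wide$pollutant[i], wide$compartment[i])
      d <- wide$kg_per_tonne.incineration[i] - wide$kg_per_tonne.steam[i]
      expected <- if (d > 0) "CP>MP>BAU>MS" else if (d < 0) "MS>BAU>MP>CP" else
        "4-way tie"
      if (d != 0) expect_equal(attr(oc, "ordering"), expected)
      else expect_equal(oc$rank, rep(1L, 4))
    }
  }
})

test_that("factor tables are validated and completed by the zero rule", {
  expect_error(as_emission_factors(data.frame(a = 1)), "columns")
  bad_tech <- data.frame(technology = "burning", pollutant = "x",
                         compartment = "air", kg_per_tonne = 1)
  expect_error(as_emission_factors(bad_tech), "technology")
  bad_dup <- data.frame(technology = rep("steam", 2), pollutant = "x",
                        compartment = "air", kg_per_tonne = 1:2)
  expect_error(as_emission_factors(bad_dup), "duplicate")
  neg <- data.frame(technology = "steam", pollutant = "x",
                    compartment = "air", kg_per_tonne = -1)
  expect_error(as_emission_factors(neg), ">= 0")
  # one-technology species gets factor 0 for the other
  one <- as_emission_factors(data.frame(technology = "steam", pollutant = "x",
                                        compartment = "air", kg_per_tonne = 2))
  expect_equal(nrow(one), 2)
  expect_equal(one$kg_per_tonne[one$technology == "incineration"], 0)
})

test_that("the bundled synthetic factor table has the documented structure", {
  ef <- synthetic_emission_factors()
  wide <- stats::reshape(as.data.frame(ef),
                         idvar = c("pollutant", "compartment"),
                         timevar = "technology", direction = "wide")
  wet <- wide$compartment %in% c("wastewater", "residue")
  # steam dominates every wastewater and residue species
  expect_true(all(wide$kg_per_tonne.steam[wet] >
                    wide$kg_per_tonne.incineration[wet]))
  air <- wide[wide$compartment == "air", ]
  # incineration dominates most gases
  expect_gt(mean(air$kg_per_tonne.incineration > air$kg_per_tonne.steam), 0.5)
  # hydrogen chloride is the largest air factor
  expect_equal(air$pollutant[which.max(air$kg_per_tonne.incineration)],
               "hydrogen_chloride")
  # nickel largest and lead smallest among the metals
  metals <- air[air$pollutant %in%
                  c("nickel", "copper", "tin", "lead", "chromium", "mercury"), ]
  expect_equal(metals$pollutant[which.max(metals$kg_per_tonne.incineration)],
               "nickel")
  expect_equal(metals$pollutant[which.min(metals$kg_per_tonne.incineration)],
               "lead")
  # chloride is the largest residue species
  resid <- wide[wide$compartment == "residue", ]
  expect_equal(resid$pollutant[which.max(resid$kg_per_tonne.steam)], "chloride")
})
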