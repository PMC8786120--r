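Package: medwaste
Title: Pandemic-Attributable Medical Waste Estimation and Disposal Scenario Emissions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates regional medical waste generation from hospital-capacity
    statistics (beds, bed utilization, visit counts) with an empirical
    generation formula, disaggregates annual totals into monthly series by
    visit shares, produces a no-epidemic counterfactual forecast with a
    from-scratch long short-term memory (LSTM) recurrent network trained by
    backpropagation through time, computes the net epidemic-attributable
    waste over an arbitrary calendar window by pro-rata day allocation, and
    assesses the environmental emissions of disposing that waste under four
    disposal-technology mix scenarios (incineration versus autoclave steam
    sterilization). Includes a synthetic-data generator that emulates the
    statistical structure of institutional panels and seasonal visit series
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
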