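Package: kitration
Title: Rationing Strategies for Rapid Diagnostic Kits Across an Epidemic Season
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and evaluates strategies for distributing a fixed
    season-opening stock of single-use rapid diagnostic kits among suspected
    patients when demand exceeds supply. Implements the hindsight "ideal"
    distribution, a prediction-based strategy driven by rolling fits of a
    single-peak (sech-squared) epidemic incidence curve, and two
    non-predictive heuristics; scores strategies against the ideal with a
    normalised stock-deviation loss; sweeps filling rates to locate the most
    efficient initial stock; and generates seeded synthetic weekly incidence
    ensembles for testing and calibration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    optparse,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
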