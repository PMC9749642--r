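Package: bedflow
Title: Stock-Flow Simulation of Hospital Bed Supply and Demand
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A system-dynamics toolkit for hospital bed capacity planning.
    Provides a deterministic stock-flow simulation engine with clamped
    piecewise-linear lookup tables and explicit Euler integration, a
    city-scale model of hospital bed supply and demand (population,
    beds, specialist physicians and home-care capacity as stocks, with
    feedback through occupancy-driven rate effects), scenario and policy
    experiments with bisection search for the minimal intervention that
    eliminates bed shortage, model validation (historical fit,
    extreme-condition and equilibrium tests, lookup-table recovery from
    data), and a synthetic-data generator for calibration exercises.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    compiler,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
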