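# Shared fixtures, built in code once per test session.

fixture_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- gen_config()
    cfg
  }
})

fixture_run <- local({
  run <- NULL
  function() {
    if (is.null(run)) run <<- simulate_config(fixture_config())
    run
  }
})

inert_config <- function() {
  gen_config(synthesis_settings(archetype = "inert"))
}

# Inert feedback AND quiet environment: no shortage under any scenario,
# so every minimal-intervention solve returns the zero policy.
quiet_config <- function() {
  cfg <- inert_config()
  bed_config(parameters = cfg$parameters,
             initial_stocks = cfg$initial_stocks,
             lookups = cfg$lookups,
             scenarios = default_scenario_presets(),
             policies = cfg$policies,
             simulation = cfg$simulation,
             synthesis = cfg$synthesis)
}

# Random monotone lookup table on a given x range. Caller controls the
# RNG state.
rand_monotone_table <- function(n_pts, xlim, direction = c("inc", "dec"),
                                ymax = 0.1, name = "F") {
  direction <- match.arg(direction)
  x <- sort(runif(n_pts, xlim[1], xlim[2]))
  while (any(diff(x) <= 1e-6)) x <- sort(runif(n_pts, xlim[1], xlim[2]))
  y <- cumsum(runif(n_pts, 0, ymax / n_pts))
  if (direction == "dec") y <- rev(y)
  lookup_table(x, y, name)
}

# Randomized-but-valid full configuration for the structural property
# suite. Deterministic in `seed`.
rand_config <- function(seed) {
  set.seed(seed)
  lk <- rate_effect_tables(
    F1 = rand_monotone_table(4, c(0, 1), "inc", ymax = 0.1, name = "F1"),
    F2 = rand_monotone_table(4, c(0.05, 0.5), "dec", ymax = 0.2,
                             name = "F2"),
    F3 = rand_monotone_table(4, c(0.005, 0.03), "dec", ymax = 0.05,
                             name = "F3"),
    F4 = {
      y <- 1 - cumsum(c(0, runif(3, 0, 0.15)))
      lookup_table(c(0, sort(runif(2, 0.05, 0.5)), 0.8), y, "F4")
    })
  bed_config(
    parameters = list(
      growth_proportion = runif(1, 0, 0.03),
      patient_to_population_ratio = runif(1, 0.1, 0.17),
      optimal_occupancy = 0.85,
      days_per_year = 365,
      travelers_to_specialists_ratio = runif(1, 30, 90),
      base_length_of_stay = runif(1, 2.5, 5)),
    initial_stocks = list(
      population = 1557600 * runif(1, 0.8, 1.2),
      number_of_bed = 3560 * runif(1, 0.8, 1.2),
      number_of_specialist_physicians = 690 * runif(1, 0.8, 1.2),
      capacity_of_home_care_services = 76650 * runif(1, 0.8, 1.2)),
    lookups = lk,
    simulation = list(start_time = 2015, stop_time = 2025,
                      dt = 1 / 12, saveper = 1 / 12))
}

# Inert-feedback toy with a small late-horizon shortage; the minimal
# bed addition is a few beds/year, so an exhaustive 0.01-resolution
# grid search is affordable as a solver oracle.
toy_shortage_config <- function() {
  config_modify(
    inert_config(),
    parameters = list(patient_to_population_ratio = 0.154),
    simulation = list(start_time = 2015, stop_time = 2025,
                      dt = 1 / 4, saveper = 1 / 4))
}

# Same toy but with an active home-care substitution table, so the
# home-care lever can absorb demand (F1-F3 stay flat).
toy_homecare_config <- function() {
  config_modify(
    toy_shortage_config(),
    parameters = list(patient_to_population_ratio = 0.162),
    lookups = rate_effect_tables(
      F1 = lookup_table(c(0, 1), c(0, 0), "F1"),
      F2 = lookup_table(c(0, 1), c(0, 0), "F2"),
      F3 = lookup_table(c(0, 0.1), c(0, 0), "F3"),
      F4 = lookup_table(c(0, 0.5), c(1, 0.6), "F4")))
}
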