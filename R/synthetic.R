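#' Synthesis settings
#'
#' Controls the synthetic-data generator that stands in for the study's
#' calibration inputs (registry extracts and the expert-derived lookup
#' tables, which are not public): a seed, the observation-noise level,
#' and an archetype selecting the steepness of the rate-effect tables
#' and the two site-specific parameters.
#'
#' @param seed Integer seed; every generated artifact is a
#'   deterministic function of it.
#' @param noise_sd Lognormal sigma of multiplicative observation noise
#'   (>= 0). Registry counts are positive with roughly proportional
#'   errors, hence the multiplicative model.
#' @param archetype `"inert"` (all feedback switched off),
#'   `"baseline_shortage"` (the default fixture: a mid-horizon shortage
#'   onset under the status quo) or `"early_shortage"` (demand close to
#'   capacity from the start).
#' @return A `synthesis_settings` object.
#' @export
synthesis_settings <- function(seed = 2015, noise_sd = 0.05,
                               archetype = c("baseline_shortage", "inert",
                                             "early_shortage")) {
  archetype <- match.arg(archetype)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), noise_sd = noise_sd,
                 archetype = archetype),
            class = "synthesis_settings")
}

# Evaluate code under a temporary RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic rate-effect lookup tables
#'
#' Monotone tables of the shapes the feedback structure requires
#' (see [rate_effect_tables()]), on fixed `x` grids: occupancy on
#' `[0, 1]`, the staffing and bed ratios on data-plausible ranges. The
#' seed applies a small deterministic scale jitter per table (the `F4`
#' anchor `F4(0) = 1` and all monotonicity constraints are preserved);
#' the archetype sets the base steepness. These tables are synthetic
#' stand-ins, not estimates of any real facility's response.
#'
#' @param archetype See [synthesis_settings()].
#' @param seed Integer seed for the jitter.
#' @return A [rate_effect_tables()] object.
#' @export
default_lookups <- function(archetype = "baseline_shortage", seed = 2015) {
  archetype <- match.arg(archetype,
                         c("baseline_shortage", "inert", "early_shortage"))
  if (archetype == "inert") {
    return(rate_effect_tables(
      F1 = lookup_table(c(0, 1), c(0, 0), "F1"),
      F2 = lookup_table(c(0, 1), c(0, 0), "F2"),
      F3 = lookup_table(c(0, 0.1), c(0, 0), "F3"),
      F4 = lookup_table(c(0, 1), c(1, 1), "F4")))
  }
  steep <- if (archetype == "early_shortage") 1.4 else 1
  base <- list(
    F1 = list(x = c(0, 0.5, 0.7, 0.85, 1),
              y = c(0, 0.002, 0.01, 0.04, 0.08)),
    F2 = list(x = c(0.05, 0.12, 0.2, 0.3, 0.5),
              y = steep * c(0.22, 0.18, 0.14, 0.08, 0.03)),
    F3 = list(x = c(0.005, 0.01, 0.0125, 0.015, 0.02, 0.03),
              y = c(0.03, 0.005, 0.002, 0.0006, 0.0002, 0.0001)),
    F4 = list(x = c(0, 0.05, 0.1, 0.25, 0.5, 0.8),
              y = c(1, 0.98, 0.94, 0.82, 0.66, 0.55))
  )
  eps <- with_seed(seed, stats::runif(4, -0.05, 0.05))
  tabs <- rate_effect_tables(
    F1 = lookup_table(base$F1$x, base$F1$y * (1 + eps[1L]), "F1"),
    F2 = lookup_table(base$F2$x, base$F2$y * (1 + eps[2L]), "F2"),
    F3 = lookup_table(base$F3$x, base$F3$y * (1 + eps[3L]), "F3"),
    F4 = lookup_table(base$F4$x, 1 - (1 - base$F4$y) * (1 + eps[4L]), "F4"))
  tabs
}

#' Generate a complete synthetic configuration
#'
#' Fills the canonical configuration with the model's reference
#' parameter and initial-stock values, archetype-dependent synthetic
#' values for the two site-specific parameters
#' (`travelers_to_specialists_ratio`, `base_length_of_stay`) and the
#' lookup tables, and synthetic environmental-scenario presets:
#' * `S2` — continued population growth with aging ramps (patient
#'   ratio and length of stay increasing),
#' * `S3` — reduced population growth with the same aging ramps,
#' * `S4` — `S2` plus a declining travelers ratio (more equitable
#'   regional physician distribution).
#'
#' The generated configuration always passes [validate_model()].
#'
#' @param settings A [synthesis_settings()].
#' @return A [bed_config()].
#' @export
gen_config <- function(settings = synthesis_settings()) {
  stopifnot(inherits(settings, "synthesis_settings"))
  site <- switch(settings$archetype,
                 inert = list(travelers = 60, los = 3.5),
                 baseline_shortage = list(travelers = 60, los = 3.5),
                 early_shortage = list(travelers = 80, los = 4.2))
  bed_config(
    parameters = list(
      growth_proportion = 0.014,
      patient_to_population_ratio = 0.129,
      optimal_occupancy = 0.85,
      days_per_year = 365,
      travelers_to_specialists_ratio = site$travelers,
      base_length_of_stay = site$los),
    initial_stocks = list(
      population = 1557600,
      number_of_bed = 3560,
      number_of_specialist_physicians = 690,
      capacity_of_home_care_services = 76650),
    lookups = default_lookups(settings$archetype, settings$seed),
    scenarios = list(
      S1 = list(patient_ratio_ramp = 0, los_ramp = 0,
                travelers_ratio_ramp = 0),
      S2 = list(patient_ratio_ramp = 0.002, los_ramp = 0.05,
                travelers_ratio_ramp = 0),
      S3 = list(growth_proportion_after = 0.007,
                patient_ratio_ramp = 0.002, los_ramp = 0.05,
                travelers_ratio_ramp = 0),
      S4 = list(patient_ratio_ramp = 0.002, los_ramp = 0.05,
                travelers_ratio_ramp = -1.5)),
    policies = list(start_year = 2020),
    simulation = list(start_time = 2015, stop_time = 2035,
                      dt = 1 / 12, saveper = 1 / 12),
    synthesis = unclass_list(settings))
}

#' Generate a noisy synthetic historical series
#'
#' Simulates the configuration noiselessly over the historical window
#' (2015 to `stop_year`), takes the annual values of the observable
#' variables (beds, specialists, occupancy rate, total patients,
#' home-care capacity), and multiplies each observation by independent
#' lognormal noise `exp(N(0, noise_sd))`. With `noise_sd = 0` the
#' history equals the model's annual values exactly.
#'
#' @param config A [bed_config()].
#' @param settings A [synthesis_settings()]; defaults to the settings
#'   recorded in `config$synthesis`.
#' @param stop_year Last observation year (default 2019).
#' @return A [historical_series()].
#' @export
gen_history <- function(config, settings = NULL, stop_year = 2019) {
  stopifnot(inherits(config, "bed_config"))
  settings <- settings %||%
    do.call(synthesis_settings, config$synthesis %||% list())
  run <- sd_simulate(config_model(config), simulation_settings(
    start_time = config$simulation$start_time,
    stop_time = stop_year,
    dt = config$simulation$dt, saveper = 1))
  vars <- c("number_of_bed", "number_of_specialist_physicians",
            "bed_occupancy_rate", "total_patient",
            "capacity_of_home_care_services")
  obs <- as.data.frame(run$values[, vars, drop = FALSE])
  if (settings$noise_sd > 0) {
    noise <- with_seed(settings$seed, matrix(
      exp(stats::rnorm(nrow(obs) * ncol(obs), 0, settings$noise_sd)),
      nrow = nrow(obs)))
    obs <- obs * noise
  }
  historical_series(run$times, obs)
}
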