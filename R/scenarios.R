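#' Scenario specification
#'
#' A scenario is an exogenous-environment assumption set: the population
#' growth proportion may switch to a new value at the scenario start
#' year, and the patient-to-population ratio, base length of stay and
#' travelers-to-specialists ratio may follow linear ramps from that
#' year. `S1` is the status-quo baseline and must have no change.
#'
#' @param id One of `"S1"`..`"S4"`.
#' @param growth_proportion_after Optional growth proportion in force
#'   from `start_year` (e.g. reduced fertility); `NULL` keeps the base
#'   value.
#' @param patient_ratio_ramp Slope added to the patient-to-population
#'   ratio, per year (population aging).
#' @param los_ramp Slope added to the base length of stay, days per year
#'   (chronic disease burden).
#' @param travelers_ratio_ramp Slope added to the travelers-to-
#'   specialists ratio, per year (may be negative under more equitable
#'   regional physician distribution).
#' @param start_year First year the environmental change acts.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(id, growth_proportion_after = NULL,
                          patient_ratio_ramp = 0, los_ramp = 0,
                          travelers_ratio_ramp = 0, start_year = 2020) {
  if (!id %in% c("S1", "S2", "S3", "S4")) {
    stop("unknown scenario id '", id, "'", call. = FALSE)
  }
  if (id == "S1" &&
      (!is.null(growth_proportion_after) || patient_ratio_ramp != 0 ||
       los_ramp != 0 || travelers_ratio_ramp != 0)) {
    stop("S1 is the baseline scenario: all ramps must be zero and the ",
         "growth proportion unchanged", call. = FALSE)
  }
  structure(list(id = id,
                 growth_proportion_after = growth_proportion_after,
                 patient_ratio_ramp = patient_ratio_ramp,
                 los_ramp = los_ramp,
                 travelers_ratio_ramp = travelers_ratio_ramp,
                 start_year = start_year),
            class = "scenario_spec")
}

#' Policy specification
#'
#' A policy is a decision-side intervention: constant exogenous annual
#' additions to the bed stock and/or the home-care capacity stock from
#' the policy start year. `P1` is no intervention, `P2` beds only, `P3`
#' home care only, `P4` both.
#'
#' @param id One of `"P1"`..`"P4"`.
#' @param bed_addition Beds added per year (>= 0).
#' @param home_care_addition Home-care service-days/year added per year
#'   (>= 0).
#' @param start_year First year the intervention acts.
#' @return A `policy_spec`.
#' @export
policy_spec <- function(id, bed_addition = 0, home_care_addition = 0,
                        start_year = 2020) {
  if (!id %in% c("P1", "P2", "P3", "P4")) {
    stop("unknown policy id '", id, "'", call. = FALSE)
  }
  if (bed_addition < 0 || home_care_addition < 0) {
    stop("policy additions must be nonnegative", call. = FALSE)
  }
  if (id == "P1" && (bed_addition != 0 || home_care_addition != 0)) {
    stop("P1 is no intervention: both additions must be zero", call. = FALSE)
  }
  if (id == "P2" && home_care_addition != 0) {
    stop("P2 adds beds only: home_care_addition must be zero", call. = FALSE)
  }
  if (id == "P3" && bed_addition != 0) {
    stop("P3 adds home care only: bed_addition must be zero", call. = FALSE)
  }
  structure(list(id = id, bed_addition = bed_addition,
                 home_care_addition = home_care_addition,
                 start_year = start_year),
            class = "policy_spec")
}

scenario_from_config <- function(config, id) {
  if (inherits(id, "scenario_spec")) return(id)
  preset <- config$scenarios[[id]]
  if (is.null(preset)) {
    stop("unknown scenario id '", id, "'", call. = FALSE)
  }
  scenario_spec(id,
                growth_proportion_after = preset$growth_proportion_after,
                patient_ratio_ramp = preset$patient_ratio_ramp,
                los_ramp = preset$los_ramp,
                travelers_ratio_ramp = preset$travelers_ratio_ramp,
                start_year = config$policies$start_year)
}

scenario_is_noop <- function(scenario, config) {
  all(c(scenario$patient_ratio_ramp, scenario$los_ramp,
        scenario$travelers_ratio_ramp) == 0) &&
    (is.null(scenario$growth_proportion_after) ||
       scenario$growth_proportion_after ==
         config$parameters$growth_proportion)
}

#' Install a scenario in a configuration
#'
#' Returns a new configuration carrying the scenario's time-varying
#' parameter paths; the input is unchanged. A no-change scenario (all
#' ramps zero, growth proportion untouched) returns the configuration
#' identically.
#'
#' @param config A [bed_config()].
#' @param scenario A scenario id (looked up in `config$scenarios`) or a
#'   [scenario_spec()].
#' @return A [bed_config()].
#' @export
apply_scenario <- function(config, scenario) {
  stopifnot(inherits(config, "bed_config"))
  scenario <- scenario_from_config(config, scenario)
  if (scenario_is_noop(scenario, config)) return(config)
  config$active_scenario <- scenario
  config
}

#' Install a policy in a configuration
#'
#' Adds the policy's constant exogenous inflows (beds and/or home-care
#' capacity) from the policy start year; the input is unchanged. The
#' no-intervention policy returns the configuration identically.
#'
#' @param config A [bed_config()].
#' @param policy A [policy_spec()] or policy id (`"P1"` only; solved
#'   policies carry their additions).
#' @return A [bed_config()].
#' @export
apply_policy <- function(config, policy) {
  stopifnot(inherits(config, "bed_config"))
  if (is.character(policy)) {
    policy <- policy_spec(policy, start_year = config$policies$start_year)
  }
  stopifnot(inherits(policy, "policy_spec"))
  if (policy$bed_addition == 0 && policy$home_care_addition == 0) {
    return(config)
  }
  config$active_policy <- policy
  config
}

#' Simulate a configuration under a scenario and policy
#'
#' @param config A [bed_config()].
#' @param scenario Scenario id or [scenario_spec()] (default baseline).
#' @param policy [policy_spec()] or policy id (default no intervention).
#' @param dt Optional integration-step override (years).
#' @return An `sd_run`.
#' @export
simulate_config <- function(config, scenario = "S1", policy = "P1",
                            dt = NULL) {
  config <- apply_scenario(config, scenario)
  config <- apply_policy(config, policy)
  sd_simulate(config_model(config), config_settings(config, dt = dt))
}

#' Time of first bed shortage
#'
#' Earliest saved time at which the shortage of bed-days exceeds the
#' threshold, expressed in years from the start of the run; `NA` if the
#' run never shows a shortage.
#'
#' @param run An `sd_run` containing a `shortage_bed_day` trajectory.
#' @param threshold Shortage threshold in bed-days/year (default 0).
#' @return Years from start (numeric) or `NA_real_`.
#' @export
first_shortage_time <- function(run, threshold = 0) {
  shortage <- run_variable(run, "shortage_bed_day")
  idx <- which(shortage > threshold)
  if (!length(idx)) return(NA_real_)
  run$times[idx[1L]] - run$times[1L]
}

#' Peak bed shortage of a run
#'
#' @param run An `sd_run` containing a `shortage_bed_day` trajectory.
#' @return Maximum shortage over the horizon (bed-days/year).
#' @export
peak_shortage <- function(run) {
  max(run_variable(run, "shortage_bed_day"))
}

# Peak shortage under a candidate (bed, home-care) intervention.
intervention_peak <- function(config, bed_addition, home_care_addition,
                              start_year) {
  pol <- policy_spec("P4", bed_addition = bed_addition,
                     home_care_addition = home_care_addition,
                     start_year = start_year)
  run <- sd_simulate(config_model(apply_policy(config, pol)),
                     config_settings(config))
  peak_shortage(run)
}

# Bisection for the minimal single-lever addition bringing peak shortage
# below tol. `f` maps the lever value to peak shortage and is assumed
# non-increasing (asserted by the caller). Returns the smallest bracket
# endpoint known feasible.
bisect_lever <- function(f, upper, tol, max_iter = 48L) {
  lo <- 0
  hi <- upper
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) <= tol) hi <- mid else lo <- mid
  }
  hi
}

#' Solve for the minimal intervention eliminating bed shortage
#'
#' Searches for the smallest constant annual addition that keeps the
#' peak shortage of bed-days at or below `tol` over the whole horizon.
#' `P2` bisects the bed lever, `P3` the home-care lever; each bracket is
#' verified before the search (the upper bound starts at ten times the
#' initial stock spread over the horizon and is doubled up to three
#' times on bracket failure), and a monotone shortage response to the
#' lever is asserted first. `P4` minimizes the bed addition over a grid
#' of home-care additions capped at `home_care_cap_fraction` of the `P3`
#' solution (home care alone is not assumed scalable without limit),
#' tie-broken by the smallest home-care addition.
#'
#' @param config A [bed_config()], typically with a scenario already
#'   applied.
#' @param policy_id `"P2"`, `"P3"` or `"P4"`.
#' @param tol Peak-shortage tolerance in bed-days/year (default 1).
#' @param grid_levels Number of home-care grid levels for `P4`.
#' @param home_care_cap_fraction Fraction of the `P3` home-care solution
#'   available to `P4`.
#' @return A [policy_spec()] with the solved additions; attributes
#'   `peak_shortage` (re-simulated) and, for `P4`, `grid` (the explored
#'   home-care levels and their minimal bed additions).
#' @export
solve_min_intervention <- function(config, policy_id, tol = 1,
                                   grid_levels = 25L,
                                   home_care_cap_fraction = 0.5) {
  stopifnot(inherits(config, "bed_config"))
  if (!policy_id %in% c("P2", "P3", "P4")) {
    stop("policy_id must be one of 'P2', 'P3', 'P4'", call. = FALSE)
  }
  start_year <- config$policies$start_year
  horizon <- config$simulation$stop_time - config$simulation$start_time

  base_peak <- intervention_peak(config, 0, 0, start_year)
  if (base_peak <= tol) {
    return(structure(policy_spec(policy_id, start_year = start_year),
                     peak_shortage = base_peak))
  }

  solve_single <- function(lever, max_iter = 48L) {
    init <- if (lever == "bed") config$initial_stocks$number_of_bed else
      config$initial_stocks$capacity_of_home_care_services
    f <- if (lever == "bed") {
      function(a) intervention_peak(config, a, 0, start_year)
    } else {
      function(a) intervention_peak(config, 0, a, start_year)
    }
    upper <- 10 * init / horizon
    tries <- 0L
    while (f(upper) > tol && tries < 3L) {
      upper <- 2 * upper
      tries <- tries + 1L
    }
    if (f(upper) > tol) {
      stop("bracket failure: ", lever, " addition of ", format(upper),
           " per year still leaves peak shortage ", format(f(upper)),
           " > tol", call. = FALSE)
    }
    # monotone-response assertion: a non-monotone peak would make the
    # bisection root meaningless, so abort rather than return it
    peaks <- c(base_peak, f(upper / 2), f(upper))
    if (any(diff(peaks) > max(tol, 1e-9 * base_peak))) {
      stop("peak shortage is not monotone in the ", lever,
           " addition; refusing to bisect (peaks: ",
           paste(format(peaks), collapse = ", "), ")", call. = FALSE)
    }
    bisect_lever(f, upper, tol, max_iter)
  }

  if (policy_id == "P2") {
    b <- solve_single("bed")
    out <- policy_spec("P2", bed_addition = b, start_year = start_year)
    attr(out, "peak_shortage") <- intervention_peak(config, b, 0, start_year)
    return(out)
  }
  if (policy_id == "P3") {
    h <- solve_single("home_care")
    out <- policy_spec("P3", home_care_addition = h, start_year = start_year)
    attr(out, "peak_shortage") <- intervention_peak(config, 0, h, start_year)
    return(out)
  }

  # P4: home-care grid capped below the P3 solution, minimal beds at
  # each level, lexicographic (beds, then home care) choice.
  h3 <- solve_single("home_care")
  h_max <- home_care_cap_fraction * h3
  h_grid <- seq(0, h_max, length.out = grid_levels)
  b_upper <- 10 * config$initial_stocks$number_of_bed / horizon
  tries <- 0L
  while (intervention_peak(config, b_upper, 0, start_year) > tol &&
         tries < 3L) {
    b_upper <- 2 * b_upper
    tries <- tries + 1L
  }
  b_grid <- vapply(h_grid, function(h) {
    f <- function(a) intervention_peak(config, a, h, start_year)
    bisect_lever(f, b_upper, tol, max_iter = 20L)
  }, 0)
  b_res <- b_upper / 2^20 # coarse-pass bed resolution
  best_b <- min(b_grid)
  j <- which(b_grid <= best_b + b_res)[1L] # tie -> smallest home care
  f_best <- function(a) intervention_peak(config, a, h_grid[j], start_year)
  b <- bisect_lever(f_best, b_upper, tol, max_iter = 48L)
  out <- policy_spec("P4", bed_addition = b,
                     home_care_addition = h_grid[j],
                     start_year = start_year)
  attr(out, "peak_shortage") <-
    intervention_peak(config, b, h_grid[j], start_year)
  attr(out, "grid") <- data.frame(home_care_addition = h_grid,
                                  bed_addition = b_grid)
  out
}

run_summary_row <- function(run, scenario_id, policy) {
  end <- nrow(run$values)
  data.frame(
    scenario = scenario_id,
    policy = policy$id,
    bed_addition = policy$bed_addition,
    home_care_addition = policy$home_care_addition,
    end_beds = unname(run$values[end, "number_of_bed"]),
    end_home_care = unname(run$values[end, "capacity_of_home_care_services"]),
    first_shortage_time = first_shortage_time(run),
    peak_shortage = peak_shortage(run),
    stringsAsFactors = FALSE
  )
}

#' Run the full scenario-by-policy experiment
#'
#' Simulates every scenario under every policy. For `P2`--`P4` the
#' minimal intervention is first solved per scenario with
#' [solve_min_intervention()]; `P1` is the uncontrolled run. The result
#' is one summary row per cell: end-of-horizon beds and home-care
#' capacity, first shortage time and peak shortage, plus the solved
#' additions. The sweep is a pure function of the configuration.
#'
#' @param config A [bed_config()].
#' @param scenarios Character vector of scenario ids.
#' @param policies Character vector of policy ids.
#' @param tol Peak-shortage tolerance passed to the solver.
#' @return A data frame of class `bed_sweep`, ordered by (scenario,
#'   policy); attribute `policies` holds the solved `policy_spec`s.
#' @export
scenario_policy_sweep <- function(config,
                                  scenarios = c("S1", "S2", "S3", "S4"),
                                  policies = c("P1", "P2", "P3", "P4"),
                                  tol = 1) {
  stopifnot(inherits(config, "bed_config"))
  rows <- list()
  solved <- list()
  for (sid in scenarios) {
    cfg_s <- apply_scenario(config, sid)
    for (pid in policies) {
      pol <- if (pid == "P1") {
        policy_spec("P1", start_year = config$policies$start_year)
      } else {
        solve_min_intervention(cfg_s, pid, tol = tol)
      }
      run <- sd_simulate(config_model(apply_policy(cfg_s, pol)),
                         config_settings(cfg_s))
      rows[[paste(sid, pid)]] <- run_summary_row(run, sid, pol)
      solved[[paste(sid, pid)]] <- pol
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$scenario, out$policy), ]
  structure(out, policies = solved, class = c("bed_sweep", "data.frame"))
}

#' Write a sweep summary as delimited text
#'
#' One row per scenario-policy cell, mirroring an end-state summary
#' table; a leading comment line names the units of every column.
#'
#' @param sweep A [scenario_policy_sweep()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_summary <- function(sweep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(
    "# bed_addition: beds/year; home_care_addition: service-days/year ",
    "per year; end_beds: beds; end_home_care: service-days/year; ",
    "first_shortage_time: years from start; peak_shortage: bed-days/year"),
    con)
  utils::write.csv(as.data.frame(sweep), con, row.names = FALSE)
  invisible(path)
}
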