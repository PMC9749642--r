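#' Parameters of the hospital-bed model
#'
#' Constants of the city-scale bed supply/demand model. The population
#' growth proportion, patient-to-population ratio, optimal occupancy and
#' the year length carry conventional defaults; the travelers-to-
#' specialists ratio and the base average length of stay are
#' site-specific and must always be supplied (the shipped synthetic
#' configurations use placeholder values, see [gen_config()]).
#'
#' @param travelers_to_specialists_ratio Patients travelling into the
#'   city per specialist per year (required).
#' @param base_length_of_stay Average hospital length of stay in days
#'   before home-care substitution (required).
#' @param growth_proportion Fractional population growth per year.
#' @param patient_to_population_ratio Patients per resident per year.
#' @param optimal_occupancy Target maximum bed occupancy rate, in (0, 1].
#' @param days_per_year Days per year (365).
#' @return A `bed_parameters` list.
#' @export
bed_parameters <- function(travelers_to_specialists_ratio,
                           base_length_of_stay,
                           growth_proportion = 0.014,
                           patient_to_population_ratio = 0.129,
                           optimal_occupancy = 0.85,
                           days_per_year = 365) {
  p <- list(growth_proportion = growth_proportion,
            patient_to_population_ratio = patient_to_population_ratio,
            optimal_occupancy = optimal_occupancy,
            days_per_year = days_per_year,
            travelers_to_specialists_ratio = travelers_to_specialists_ratio,
            base_length_of_stay = base_length_of_stay)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("parameter '", nm, "' must be a single finite nonnegative number",
           call. = FALSE)
    }
  }
  if (!(p$optimal_occupancy > 0 && p$optimal_occupancy <= 1)) {
    stop("optimal_occupancy must lie in (0, 1]", call. = FALSE)
  }
  if (p$days_per_year != 365) {
    stop("days_per_year must be 365", call. = FALSE)
  }
  structure(p, class = "bed_parameters")
}

#' Initial stock values of the hospital-bed model
#'
#' Defaults are the model's reference city: 1,557,600 residents, 3560
#' hospital beds, 690 specialist physicians and 76,650 home-care
#' service-days per year.
#'
#' @param population Residents.
#' @param number_of_bed Hospital beds.
#' @param number_of_specialist_physicians Specialist physicians.
#' @param capacity_of_home_care_services Home-care service-days per year.
#' @return A `bed_initial_stocks` list.
#' @export
bed_initial_stocks <- function(population = 1557600,
                               number_of_bed = 3560,
                               number_of_specialist_physicians = 690,
                               capacity_of_home_care_services = 76650) {
  s <- list(population = population,
            number_of_bed = number_of_bed,
            number_of_specialist_physicians = number_of_specialist_physicians,
            capacity_of_home_care_services = capacity_of_home_care_services)
  for (nm in names(s)) {
    v <- s[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("initial stock '", nm,
           "' must be a single finite nonnegative number", call. = FALSE)
    }
  }
  structure(s, class = "bed_initial_stocks")
}

#' Rate-effect lookup tables
#'
#' The four graphical functions that close the model's feedback loops:
#' * `F1(bed occupancy rate)` — fractional growth rate of home-care
#'   capacity per year; non-decreasing (higher occupancy motivates
#'   home-care providers).
#' * `F2(specialist-to-bed ratio)` — fractional growth rate of
#'   specialists per year; non-increasing (scarce specialists per bed
#'   attract more).
#' * `F3(bed-to-patient ratio)` — fractional growth rate of beds per
#'   year; non-increasing (scarce beds per patient drive construction).
#' * `F4(home-care share)` — multiplier on the base length of stay;
#'   non-increasing with `F4(0) = 1` (no home care leaves the stay
#'   unadjusted; more home care shortens it).
#'
#' @param F1,F2,F3,F4 [lookup_table()] objects satisfying the shape
#'   constraints above.
#' @return A `rate_effect_tables` list.
#' @export
rate_effect_tables <- function(F1, F2, F3, F4) {
  for (nm in c("F1", "F2", "F3", "F4")) {
    tbl <- get(nm, inherits = FALSE)
    if (!inherits(tbl, "lookup_table")) {
      stop(nm, " must be a lookup_table", call. = FALSE)
    }
  }
  if (!lookup_nondecreasing(F1)) {
    stop("F1 must be non-decreasing in occupancy", call. = FALSE)
  }
  if (!lookup_nonincreasing(F2)) {
    stop("F2 must be non-increasing in the specialist-to-bed ratio",
         call. = FALSE)
  }
  if (!lookup_nonincreasing(F3)) {
    stop("F3 must be non-increasing in the bed-to-patient ratio",
         call. = FALSE)
  }
  if (!lookup_nonincreasing(F4)) {
    stop("F4 must be non-increasing in the home-care share", call. = FALSE)
  }
  if (abs(lookup_eval(F4, 0) - 1) > 1e-12) {
    stop("F4(0) must equal 1 (no home care leaves the stay unadjusted)",
         call. = FALSE)
  }
  F1$name <- "F1"; F2$name <- "F2"; F3$name <- "F3"; F4$name <- "F4"
  structure(list(F1 = F1, F2 = F2, F3 = F3, F4 = F4),
            class = "rate_effect_tables")
}

# Language helper: parameter either constant or scenario-driven path.
param_or_path <- function(name, base, units, ramp = 0, start = 2020,
                          clamp = FALSE) {
  if (ramp == 0) return(sd_param(name, base, units))
  eqn <- bquote(.(base) + RAMP(.(ramp), .(start)))
  if (clamp) eqn <- bquote(MAX(0, .(eqn)))
  sd_aux(name, eqn, units)
}

#' Build the hospital-bed stock-flow model
#'
#' Assembles the full equation system: demand (patients from residents
#' plus travelers, bed-days required via the length of stay, occupancy
#' capped at the optimal rate, shortage as the excess demand) and supply
#' (beds, specialists and home-care capacity growing as
#' `stock * rate_effect`, each rate effect read from its lookup table).
#' Home care feeds back on demand by scaling the length of stay through
#' `F4` of the home-care share (home-care service-days over total
#' bed-days).
#'
#' Scenarios install time-varying parameter paths (linear ramps and a
#' population-growth switch from the intervention start year); policies
#' add constant exogenous inflows to the bed and home-care stocks from
#' their start year.
#'
#' @param params A [bed_parameters()] object.
#' @param init A [bed_initial_stocks()] object.
#' @param lookups A [rate_effect_tables()] object.
#' @param scenario Optional [scenario_spec()].
#' @param policy Optional [policy_spec()].
#' @return An [sd_model()] that validates cleanly.
#' @export
build_bed_model <- function(params, init, lookups,
                            scenario = NULL, policy = NULL) {
  if (!inherits(params, "bed_parameters")) {
    params <- do.call(bed_parameters, as.list(params))
  }
  if (!inherits(init, "bed_initial_stocks")) {
    init <- do.call(bed_initial_stocks, as.list(init))
  }
  if (!inherits(lookups, "rate_effect_tables")) {
    lookups <- do.call(rate_effect_tables, lookups[c("F1", "F2", "F3", "F4")])
  }

  s_start <- 2020
  ramps <- list(patient = 0, los = 0, travelers = 0)
  growth_var <- sd_param("growth_proportion", params$growth_proportion,
                         "fraction/year")
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "scenario_spec"))
    s_start <- scenario$start_year
    ramps <- list(patient = scenario$patient_ratio_ramp,
                  los = scenario$los_ramp,
                  travelers = scenario$travelers_ratio_ramp)
    if (!is.null(scenario$growth_proportion_after) &&
        scenario$growth_proportion_after != params$growth_proportion) {
      growth_var <- sd_aux(
        "growth_proportion",
        bquote(IF_THEN_ELSE(TIME >= .(s_start),
                            .(scenario$growth_proportion_after),
                            .(params$growth_proportion))),
        "fraction/year")
    }
  }

  bed_inflows <- "bed_increase_rate"
  hc_inflows <- "home_care_increase_rate"
  extra <- list()
  if (!is.null(policy)) {
    stopifnot(inherits(policy, "policy_spec"))
    p_start <- policy$start_year
    if (policy$bed_addition > 0) {
      extra <- c(extra, list(sd_flow(
        "bed_policy_addition",
        bquote(STEP(.(policy$bed_addition), .(p_start))), "beds/year")))
      bed_inflows <- c(bed_inflows, "bed_policy_addition")
    }
    if (policy$home_care_addition > 0) {
      extra <- c(extra, list(sd_flow(
        "home_care_policy_addition",
        bquote(STEP(.(policy$home_care_addition), .(p_start))),
        "service-days/year/year")))
      hc_inflows <- c(hc_inflows, "home_care_policy_addition")
    }
  }

  sd_model(
    # stocks
    sd_stock("population", init$population, inflows = "growth_rate",
             units = "persons"),
    sd_stock("number_of_bed", init$number_of_bed, inflows = bed_inflows,
             units = "beds"),
    sd_stock("number_of_specialist_physicians",
             init$number_of_specialist_physicians,
             inflows = "specialist_increase_rate", units = "specialists"),
    sd_stock("capacity_of_home_care_services",
             init$capacity_of_home_care_services,
             inflows = hc_inflows, units = "service-days/year"),
    # parameters (possibly scenario-driven paths)
    growth_var,
    param_or_path("patient_to_population_ratio",
                  params$patient_to_population_ratio,
                  "patients/person/year", ramps$patient, s_start),
    param_or_path("base_length_of_stay", params$base_length_of_stay,
                  "days", ramps$los, s_start, clamp = TRUE),
    param_or_path("travelers_to_specialists_ratio",
                  params$travelers_to_specialists_ratio,
                  "patients/specialist/year", ramps$travelers, s_start,
                  clamp = TRUE),
    sd_param("optimal_occupancy", params$optimal_occupancy, "fraction"),
    sd_param("days_per_year", params$days_per_year, "days"),
    # lookups
    sd_lookup("F1", lookups$F1), sd_lookup("F2", lookups$F2),
    sd_lookup("F3", lookups$F3), sd_lookup("F4", lookups$F4),
    # demand side
    sd_flow("growth_rate", quote(growth_proportion * population),
            "persons/year"),
    sd_aux("flow_of_travelers",
           quote(number_of_specialist_physicians *
                   travelers_to_specialists_ratio), "patients/year"),
    sd_aux("total_patient",
           quote(flow_of_travelers +
                   population * patient_to_population_ratio),
           "patients/year"),
    sd_aux("total_bed_day", quote(number_of_bed * days_per_year),
           "bed-days/year"),
    sd_aux("home_care_share",
           quote(capacity_of_home_care_services / total_bed_day),
           "fraction"),
    sd_aux("rate_effect_4", quote(F4(home_care_share)), "dimensionless"),
    sd_aux("length_of_stay", quote(base_length_of_stay * rate_effect_4),
           "days"),
    sd_aux("total_bed_day_required", quote(total_patient * length_of_stay),
           "bed-days/year"),
    sd_aux("bed_occupancy_day",
           quote(IF_THEN_ELSE(
             total_bed_day_required <= total_bed_day * optimal_occupancy,
             total_bed_day_required,
             total_bed_day * optimal_occupancy)), "bed-days/year"),
    sd_aux("bed_occupancy_rate", quote(bed_occupancy_day / total_bed_day),
           "fraction"),
    sd_aux("shortage_bed_day",
           quote(MAX(0, total_bed_day_required -
                       optimal_occupancy * total_bed_day)),
           "bed-days/year"),
    # supply side
    sd_aux("specialist_to_bed_ratio",
           quote(number_of_specialist_physicians / number_of_bed),
           "specialists/bed"),
    sd_aux("bed_to_patient_ratio", quote(number_of_bed / total_patient),
           "beds/patient"),
    sd_aux("rate_effect_1", quote(F1(bed_occupancy_rate)), "fraction/year"),
    sd_aux("rate_effect_2", quote(F2(specialist_to_bed_ratio)),
           "fraction/year"),
    sd_aux("rate_effect_3", quote(F3(bed_to_patient_ratio)), "fraction/year"),
    sd_flow("bed_increase_rate", quote(number_of_bed * rate_effect_3),
            "beds/year"),
    sd_flow("specialist_increase_rate",
            quote(number_of_specialist_physicians * rate_effect_2),
            "specialists/year"),
    sd_flow("home_care_increase_rate",
            quote(capacity_of_home_care_services * rate_effect_1),
            "service-days/year/year"),
    extra
  )
}

#' Evaluate the demand-side auxiliaries
#'
#' Pure static evaluation of the demand block: total patients (residents
#' times the patient ratio plus travelers), total bed-days supplied and
#' required, occupancy capped at the optimal rate, and the resulting
#' shortage.
#'
#' @param population Residents.
#' @param specialists Specialist physicians (drives the travelers term).
#' @param beds Hospital beds.
#' @param length_of_stay Effective average length of stay (days).
#' @param params A [bed_parameters()] object.
#' @return Named list with `total_patient`, `total_bed_day`,
#'   `total_bed_day_required`, `bed_occupancy_day`, `bed_occupancy_rate`
#'   and `shortage_bed_day`.
#' @export
eval_demand_block <- function(population, specialists, beds, length_of_stay,
                              params) {
  stopifnot(inherits(params, "bed_parameters"))
  stopifnot(population >= 0, specialists >= 0, beds >= 0, length_of_stay >= 0)
  flow_of_travelers <- specialists * params$travelers_to_specialists_ratio
  total_patient <- flow_of_travelers +
    population * params$patient_to_population_ratio
  total_bed_day <- beds * params$days_per_year
  total_bed_day_required <- total_patient * length_of_stay
  cap <- total_bed_day * params$optimal_occupancy
  bed_occupancy_day <- if (total_bed_day_required <= cap)
    total_bed_day_required else cap
  bed_occupancy_rate <- if (total_bed_day == 0) {
    warning("division by zero in 'bed_occupancy_rate'; value set to 0",
            call. = FALSE)
    0
  } else bed_occupancy_day / total_bed_day
  shortage_bed_day <- max(0, total_bed_day_required - cap)
  list(total_patient = total_patient,
       total_bed_day = total_bed_day,
       total_bed_day_required = total_bed_day_required,
       bed_occupancy_day = bed_occupancy_day,
       bed_occupancy_rate = bed_occupancy_rate,
       shortage_bed_day = shortage_bed_day)
}

#' Evaluate the growth-side auxiliaries
#'
#' Reads the four rate effects off their lookup tables at the current
#' drivers and forms the three capacity inflows (`stock * fractional
#' rate`) and the home-care-adjusted length of stay.
#'
#' @param stocks Named list/vector with `number_of_bed`,
#'   `number_of_specialist_physicians` and
#'   `capacity_of_home_care_services`.
#' @param demand Demand block as returned by [eval_demand_block()].
#' @param lookups A [rate_effect_tables()] object.
#' @param params A [bed_parameters()] object.
#' @return Named list with the four rate effects, the three inflow
#'   rates, and `length_of_stay`.
#' @export
eval_growth_block <- function(stocks, demand, lookups, params) {
  stopifnot(inherits(lookups, "rate_effect_tables"),
            inherits(params, "bed_parameters"))
  stocks <- as.list(stocks)
  beds <- stocks$number_of_bed
  specs <- stocks$number_of_specialist_physicians
  hc <- stocks$capacity_of_home_care_services
  specialist_to_bed_ratio <- if (beds == 0) 0 else specs / beds
  bed_to_patient_ratio <- if (demand$total_patient == 0) 0 else
    beds / demand$total_patient
  home_care_share <- if (demand$total_bed_day == 0) 0 else
    hc / demand$total_bed_day
  rate_effect_1 <- lookup_eval(lookups$F1, demand$bed_occupancy_rate)
  rate_effect_2 <- lookup_eval(lookups$F2, specialist_to_bed_ratio)
  rate_effect_3 <- lookup_eval(lookups$F3, bed_to_patient_ratio)
  rate_effect_4 <- lookup_eval(lookups$F4, home_care_share)
  list(rate_effect_1 = rate_effect_1,
       rate_effect_2 = rate_effect_2,
       rate_effect_3 = rate_effect_3,
       rate_effect_4 = rate_effect_4,
       bed_increase_rate = beds * rate_effect_3,
       specialist_increase_rate = specs * rate_effect_2,
       home_care_increase_rate = hc * rate_effect_1,
       length_of_stay = params$base_length_of_stay * rate_effect_4)
}
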