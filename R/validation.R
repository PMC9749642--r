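#' Historical observation series
#'
#' Annual observations of model variables (typically beds, specialists,
#' occupancy rate, total patients and home-care capacity) used for
#' historical-fit validation and lookup-table recovery.
#'
#' @param years Strictly increasing integer years, length >= 2.
#' @param observed Named list or data frame: one numeric vector per
#'   observed variable, same length as `years`, nonnegative.
#' @return A `historical_series` object.
#' @export
historical_series <- function(years, observed) {
  years <- as.numeric(years)
  if (length(years) < 2L || any(diff(years) <= 0)) {
    stop("need >= 2 strictly increasing years", call. = FALSE)
  }
  observed <- as.data.frame(observed, check.names = FALSE)
  if (nrow(observed) != length(years)) {
    stop("observed values must have one row per year", call. = FALSE)
  }
  for (nm in names(observed)) {
    v <- observed[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      stop("observed '", nm, "' must be finite and nonnegative",
           call. = FALSE)
    }
  }
  structure(list(years = years, observed = observed),
            class = "historical_series")
}

#' @export
print.historical_series <- function(x, ...) {
  cat("<historical_series> ", length(x$years), " years (",
      x$years[1], "-", x$years[length(x$years)], "), variables: ",
      paste(names(x$observed), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write a historical series as delimited text
#'
#' CSV with a `year` column and one column per observed variable; a
#' leading comment line names the units convention.
#'
#' @param hist A [historical_series()].
#' @param path File path.
#' @return `path` invisibly; `read_history` returns a
#'   [historical_series()].
#' @export
write_history <- function(hist, path) {
  stopifnot(inherits(hist, "historical_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# year: calendar year; remaining columns in model units",
             con)
  utils::write.csv(data.frame(year = hist$years, hist$observed,
                              check.names = FALSE),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"year" %in% names(df)) {
    stop("history file must have a 'year' column", call. = FALSE)
  }
  historical_series(df$year, df[setdiff(names(df), "year")])
}

#' Compare a simulated run against historical observations
#'
#' Aligns the run's saved values to the observation years and reports,
#' per shared variable, the mean absolute percentage error (MAPE) and
#' the root-mean-square error (RMSE). Observations equal to zero are
#' excluded from MAPE with a warning (the percentage error is
#' undefined there).
#'
#' @param run An `sd_run` whose saved times cover the history years.
#' @param hist A [historical_series()].
#' @return A `fit_metrics` data frame with columns `variable`, `mape`
#'   (percent) and `rmse`; attribute `worst_mape` carries the largest
#'   per-variable MAPE.
#' @export
compare_to_history <- function(run, hist) {
  stopifnot(inherits(run, "sd_run"), inherits(hist, "historical_series"))
  idx <- vapply(hist$years, function(y) {
    i <- which(abs(run$times - y) < 1e-6)
    if (!length(i)) {
      stop("run does not save time point ", y, call. = FALSE)
    }
    i[1L]
  }, 0L)
  shared <- intersect(names(hist$observed), colnames(run$values))
  if (!length(shared)) {
    stop("run and history share no variables", call. = FALSE)
  }
  rows <- lapply(shared, function(nm) {
    sim <- run$values[idx, nm]
    obs <- hist$observed[[nm]]
    keep <- obs != 0
    if (any(!keep)) {
      warning("excluding ", sum(!keep), " zero observation(s) of '", nm,
              "' from MAPE", call. = FALSE)
    }
    data.frame(
      variable = nm,
      mape = if (any(keep))
        100 * mean(abs(sim[keep] - obs[keep]) / abs(obs[keep])) else NA_real_,
      rmse = sqrt(mean((sim - obs)^2)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, worst_mape = max(out$mape, na.rm = TRUE),
            class = c("fit_metrics", "data.frame"))
}

#' Derive a modified configuration
#'
#' Returns a new configuration with selected entries overridden and
#' everything revalidated; the input is unchanged. This is the building
#' block of the extreme-condition and equilibrium tests and convenient
#' for sensitivity experiments.
#'
#' @param config A [bed_config()].
#' @param parameters,initial_stocks,simulation Named lists of entries
#'   to override (merged into the existing sections).
#' @param lookups Optional replacement [rate_effect_tables()].
#' @return A [bed_config()].
#' @export
config_modify <- function(config, parameters = list(),
                          initial_stocks = list(), lookups = NULL,
                          simulation = list()) {
  p <- utils::modifyList(config$parameters, parameters)
  s <- utils::modifyList(config$initial_stocks, initial_stocks)
  sim <- utils::modifyList(config$simulation, simulation)
  lk <- if (is.null(lookups)) config$lookups else lookups
  out <- bed_config(parameters = p, initial_stocks = s, lookups = lk,
                    scenarios = config$scenarios,
                    policies = config$policies,
                    simulation = sim,
                    synthesis = config$synthesis)
  out$active_scenario <- config$active_scenario
  out$active_policy <- config$active_policy
  out
}

inert_lookups <- function(lookups) {
  flat <- function(tbl, y) lookup_table(range(tbl$x), c(y, y), tbl$name)
  rate_effect_tables(F1 = flat(lookups$F1, 0), F2 = flat(lookups$F2, 0),
                     F3 = flat(lookups$F3, 0), F4 = flat(lookups$F4, 1))
}

#' Extreme-condition (marginal limit) test suite
#'
#' Behavioural validity checks at the margins of the model's operating
#' range: each check perturbs the configuration to a limiting condition,
#' simulates, and verifies the qualitative response. The input
#' configuration is never mutated.
#'
#' * `zero_population` — with no residents, all patients are travelers.
#' * `zero_demand` — with no patient sources, the shortage is zero
#'   throughout.
#' * `abundant_beds` — with beds scaled a thousandfold, occupancy is
#'   near zero at the start and no shortage ever appears.
#' * `zero_length_of_stay` — with a zero base stay, no bed-days are
#'   required.
#'
#' @param config A [bed_config()].
#' @return A data frame of class `validity_report`: columns `check`,
#'   `pass`, `detail`.
#' @export
extreme_condition_suite <- function(config) {
  stopifnot(inherits(config, "bed_config"))
  run_of <- function(cfg) sd_simulate(config_model(cfg),
                                      config_settings(cfg))
  checks <- list()

  r <- run_of(config_modify(config, initial_stocks = list(population = 0)))
  dev <- max(abs(run_variable(r, "total_patient") -
                   run_variable(r, "flow_of_travelers")))
  checks$zero_population <- list(
    pass = dev <= 1e-9 * max(1, max(run_variable(r, "total_patient"))),
    detail = paste0("max |total_patient - flow_of_travelers| = ",
                    format(dev)))

  r <- suppressWarnings(run_of(config_modify(
    config, parameters = list(patient_to_population_ratio = 0,
                              travelers_to_specialists_ratio = 0))))
  peak <- max(run_variable(r, "shortage_bed_day"))
  checks$zero_demand <- list(
    pass = peak == 0,
    detail = paste0("peak shortage = ", format(peak)))

  big <- config_modify(config, initial_stocks = list(
    number_of_bed = 1000 * config$initial_stocks$number_of_bed))
  r <- run_of(big)
  occ0 <- run_variable(r, "bed_occupancy_rate")[1L]
  peak <- max(run_variable(r, "shortage_bed_day"))
  checks$abundant_beds <- list(
    pass = occ0 < 0.01 && peak == 0,
    detail = paste0("initial occupancy = ", format(occ0),
                    "; peak shortage = ", format(peak)))

  r <- run_of(config_modify(config,
                            parameters = list(base_length_of_stay = 0)))
  req <- max(run_variable(r, "total_bed_day_required"))
  checks$zero_length_of_stay <- list(
    pass = req == 0,
    detail = paste0("max total_bed_day_required = ", format(req)))

  out <- data.frame(
    check = names(checks),
    pass = vapply(checks, `[[`, TRUE, "pass"),
    detail = vapply(checks, `[[`, "", "detail"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("validity_report", "data.frame"))
}

#' Equilibrium test
#'
#' With zero population growth, all rate effects flattened to zero
#' (`F4` to one) and no interventions, every stock must hold its initial
#' value over the whole horizon (relative drift below 1e-9). The check
#' is pure: the input configuration is not modified.
#'
#' @param config A [bed_config()].
#' @return A data frame of class `validity_report` with one row per
#'   stock (`check`, `pass`, `detail`); attribute `max_drift` carries
#'   the worst relative drift.
#' @export
equilibrium_test <- function(config) {
  stopifnot(inherits(config, "bed_config"))
  eq <- config_modify(config, parameters = list(growth_proportion = 0),
                      lookups = inert_lookups(config$lookups))
  eq$active_scenario <- NULL
  eq$active_policy <- NULL
  run <- sd_simulate(config_model(eq), config_settings(eq))
  stocks <- c("population", "number_of_bed",
              "number_of_specialist_physicians",
              "capacity_of_home_care_services")
  drift <- vapply(stocks, function(s) {
    x <- run_variable(run, s)
    max(abs(x - x[1L])) / max(1, abs(x[1L]))
  }, 0)
  out <- data.frame(
    check = paste0("equilibrium_", stocks),
    pass = drift < 1e-9,
    detail = paste0("relative drift = ", format(drift)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, max_drift = max(drift),
            class = c("validity_report", "data.frame"))
}

#' Recover lookup-table ordinates from observed trajectories
#'
#' Fits the free `y` values of one rate-effect table by nested
#' simulation least squares: each candidate table is installed in the
#' configuration, the model is simulated over the observation years,
#' and the squared relative error against the observations is
#' minimized. Monotonicity of the fitted table is enforced by
#' reparameterization (cumulative signed squared increments), and the
#' derivative-free Nelder-Mead simplex is used because the objective is
#' non-smooth where the occupancy cap engages. Free ordinates to which
#' the objective is insensitive (e.g. an inert feedback loop) are
#' reported as under-determined rather than silently returned.
#'
#' @param config A [bed_config()]; its other three tables are held
#'   fixed.
#' @param hist A [historical_series()] of annual observations.
#' @param target Which table to fit: `"F1"`..`"F4"`.
#' @param skeleton_x Fixed `x` grid of the fitted table; defaults to
#'   the target table's current breakpoints.
#' @param y_init Starting ordinates (defaults to the current table
#'   evaluated on `skeleton_x`).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return A `lookup_fit` list: `table` (fitted [lookup_table()]),
#'   `residual_norm`, `objective`, `convergence`,
#'   `underdetermined` (logical per ordinate) and `n_obs`.
#' @export
recover_lookup_slopes <- function(config, hist, target,
                                  skeleton_x = NULL, y_init = NULL,
                                  maxit = 1000L) {
  stopifnot(inherits(config, "bed_config"),
            inherits(hist, "historical_series"))
  if (!target %in% c("F1", "F2", "F3", "F4")) {
    stop("target must be one of 'F1'..'F4'", call. = FALSE)
  }
  cur <- config$lookups[[target]]
  skeleton_x <- skeleton_x %||% cur$x
  k <- length(skeleton_x)
  if (k < 2L) stop("skeleton needs >= 2 breakpoints", call. = FALSE)
  y_init <- y_init %||% lookup_eval(cur, skeleton_x)

  nondecreasing <- target == "F1"
  anchored <- target == "F4" && abs(skeleton_x[1L]) < 1e-12

  # theta -> monotone y: first ordinate (unless anchored at 1) plus
  # squared increments, signed by the table's direction.
  sgn <- if (nondecreasing) 1 else -1
  theta_to_y <- function(theta) {
    if (anchored) {
      y1 <- 1
      d <- theta
    } else {
      y1 <- theta[1L]
      d <- theta[-1L]
    }
    y1 + sgn * cumsum(c(0, d^2))
  }
  y_to_theta <- function(y) {
    d <- sqrt(pmax(sgn * diff(y), 0))
    if (anchored) d else c(y[1L], d)
  }

  sim_settings <- simulation_settings(
    start_time = config$simulation$start_time,
    stop_time = max(hist$years),
    dt = config$simulation$dt, saveper = 1)

  # compile once; candidate tables only swap the target's closure in
  # the compiled environment (they are monotone by construction)
  cm <- compile_model(config_model(config))
  objective <- function(theta) {
    y <- theta_to_y(theta)
    cm$env[[target]] <- make_lookup_fun(lookup_table(skeleton_x, y, target))
    run <- tryCatch(
      simulate_compiled(cm, sim_settings),
      error = function(e) NULL)
    if (is.null(run)) return(1e12)
    idx <- match(round(hist$years, 6), round(run$times, 6))
    sh <- intersect(names(hist$observed), colnames(run$values))
    err <- 0
    for (nm in sh) {
      obs <- hist$observed[[nm]]
      sc <- mean(abs(obs))
      if (sc == 0) sc <- 1
      err <- err + sum(((run$values[idx, nm] - obs) / sc)^2)
    }
    err
  }

  theta0 <- y_to_theta(y_init)
  n_free <- length(theta0)
  n_obs <- length(hist$years) * ncol(hist$observed)
  if (n_obs < n_free) {
    warning("fewer observations (", n_obs, ") than free ordinates (",
            n_free, "); fit is under-determined", call. = FALSE)
  }

  # sensitivity screen: ordinates the data cannot see are flagged
  # instead of being returned as if identified
  sens_at <- function(theta) {
    f0 <- objective(theta)
    y0 <- theta_to_y(theta)
    sens <- vapply(seq_len(k), function(i) {
      y_pert <- y0
      step <- max(1e-3, 1e-2 * abs(y0[i]))
      y_pert[i] <- y0[i] + sgn * step
      y_pert <- if (nondecreasing) cummax(y_pert) else cummin(y_pert)
      if (anchored) y_pert[1L] <- 1
      abs(objective(y_to_theta(y_pert)) - f0)
    }, 0)
    out <- sens <= 1e-12 * (1 + f0)
    if (anchored) out[1L] <- FALSE # fixed, not fitted
    out
  }
  underdetermined <- sens_at(theta0)
  f0 <- objective(theta0)
  y0 <- theta_to_y(theta0)

  if (all(underdetermined)) {
    warning("objective is insensitive to every free ordinate of ", target,
            " (inert loop?); returning the starting table", call. = FALSE)
    return(structure(list(
      table = lookup_table(skeleton_x, y0, target),
      residual_norm = sqrt(f0), objective = f0, convergence = NA_integer_,
      underdetermined = underdetermined, n_obs = n_obs),
      class = "lookup_fit"))
  }

  ctrl <- list(maxit = maxit, reltol = 1e-12)
  fit <- stats::optim(theta0, objective, method = "Nelder-Mead",
                      control = ctrl)
  fit <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                      control = ctrl) # simplex restart
  y_hat <- theta_to_y(fit$par)
  underdetermined <- sens_at(fit$par) # re-screen where the fit landed
  structure(list(
    table = lookup_table(skeleton_x, y_hat, target),
    residual_norm = sqrt(fit$value),
    objective = fit$value,
    convergence = fit$convergence,
    underdetermined = underdetermined,
    n_obs = n_obs),
    class = "lookup_fit")
}

#' @export
print.lookup_fit <- function(x, ...) {
  cat("<lookup_fit> ", x$table$name, ": residual norm ",
      format(x$residual_norm), ", ", sum(x$underdetermined),
      " under-determined ordinate(s)\n", sep = "")
  print(data.frame(x = x$table$x, y = x$table$y,
                   underdetermined = x$underdetermined),
        row.names = FALSE)
  invisible(x)
}
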