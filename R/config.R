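#' Canonical model configuration
#'
#' One structured document fully determines a bed-model experiment:
#' parameters, initial stocks, the four rate-effect lookup tables,
#' scenario presets, policy settings and simulation settings. Unknown
#' keys are errors (fail-fast), so typos cannot silently change an
#' experiment.
#'
#' @param parameters Named list accepted by [bed_parameters()].
#' @param initial_stocks Named list accepted by [bed_initial_stocks()].
#' @param lookups Named list with `F1`..`F4`, each a [lookup_table()] or
#'   a list with elements `x` and `y` (or `points`, a list of
#'   `c(x, y)` pairs).
#' @param scenarios Named list of scenario presets (`S1`..`S4`), each
#'   with `patient_ratio_ramp`, `los_ramp`, `travelers_ratio_ramp` and
#'   optionally `growth_proportion_after`.
#' @param policies List with `start_year` (first year interventions and
#'   scenario ramps act; default 2020).
#' @param simulation Named list accepted by [simulation_settings()].
#' @param synthesis Optional named list accepted by
#'   [synthesis_settings()] recording how a synthetic config was made.
#' @return A `bed_config` object.
#' @export
bed_config <- function(parameters, initial_stocks, lookups,
                       scenarios = default_scenario_presets(),
                       policies = list(start_year = 2020),
                       simulation = list(start_time = 2015,
                                         stop_time = 2035,
                                         dt = 1 / 12, saveper = 1 / 12),
                       synthesis = NULL) {
  params <- do.call(bed_parameters, parameters)
  init <- do.call(bed_initial_stocks, initial_stocks)
  lk <- coerce_lookups(lookups)
  check_keys(policies, c("start_year"), "policies")
  stopifnot(is.numeric(policies$start_year))
  settings <- do.call(simulation_settings, simulation)
  scen <- lapply(names(scenarios), function(id) {
    s <- scenarios[[id]]
    check_keys(s, c("growth_proportion_after", "patient_ratio_ramp",
                    "los_ramp", "travelers_ratio_ramp"),
               paste0("scenarios$", id))
    list(growth_proportion_after = s$growth_proportion_after,
         patient_ratio_ramp = s$patient_ratio_ramp %||% 0,
         los_ramp = s$los_ramp %||% 0,
         travelers_ratio_ramp = s$travelers_ratio_ramp %||% 0)
  })
  names(scen) <- names(scenarios)
  if (!is.null(synthesis)) synthesis <- do.call(synthesis_settings, synthesis)
  structure(list(parameters = unclass_list(params),
                 initial_stocks = unclass_list(init),
                 lookups = lk,
                 scenarios = scen,
                 policies = list(start_year = policies$start_year),
                 simulation = unclass_list(settings),
                 synthesis = if (is.null(synthesis)) NULL else
                   unclass_list(synthesis)),
            class = "bed_config")
}

unclass_list <- function(x) {
  x <- unclass(x)
  attributes(x) <- list(names = names(x))
  x
}

check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible())
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown key(s) in ", where, ": ",
         paste0("'", extra, "'", collapse = ", "), call. = FALSE)
  }
  invisible()
}

coerce_lookups <- function(lookups) {
  check_keys(lookups, c("F1", "F2", "F3", "F4"), "lookups")
  missing <- setdiff(c("F1", "F2", "F3", "F4"), names(lookups))
  if (length(missing)) {
    stop("lookups must define ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tabs <- lapply(c("F1", "F2", "F3", "F4"), function(nm) {
    tbl <- lookups[[nm]]
    if (inherits(tbl, "lookup_table")) {
      tbl$name <- nm
      return(tbl)
    }
    if (!is.null(tbl$points)) {
      pts <- do.call(rbind, lapply(tbl$points, function(p) {
        if (length(p) != 2L) {
          stop("lookups$", nm, ": each point must be an [x, y] pair",
               call. = FALSE)
        }
        as.numeric(p)
      }))
      return(lookup_table(pts[, 1L], pts[, 2L], nm))
    }
    if (!is.null(tbl$x) && !is.null(tbl$y)) {
      return(lookup_table(tbl$x, tbl$y, nm))
    }
    stop("lookups$", nm, " must be a lookup_table, an x/y list, ",
         "or a list of [x, y] points", call. = FALSE)
  })
  names(tabs) <- c("F1", "F2", "F3", "F4")
  do.call(rate_effect_tables, tabs)
}

#' Scenario presets with no environmental change
#'
#' The baseline preset set: every scenario slot present, all ramps zero.
#' [gen_config()] replaces S2--S4 with the synthetic environmental
#' assumptions.
#' @return Named list of four scenario presets.
#' @export
default_scenario_presets <- function() {
  empty <- list(growth_proportion_after = NULL, patient_ratio_ramp = 0,
                los_ramp = 0, travelers_ratio_ramp = 0)
  list(S1 = empty, S2 = empty, S3 = empty, S4 = empty)
}

config_parameters <- function(config) {
  do.call(bed_parameters, config$parameters)
}

config_initial_stocks <- function(config) {
  do.call(bed_initial_stocks, config$initial_stocks)
}

config_settings <- function(config, dt = NULL) {
  sim <- config$simulation
  if (!is.null(dt)) {
    sim$dt <- dt
    sim$saveper <- dt
  }
  do.call(simulation_settings, sim)
}

#' Build the model defined by a configuration
#'
#' @param config A [bed_config()], possibly carrying an active scenario
#'   or policy installed with [apply_scenario()] / [apply_policy()].
#' @return An [sd_model()].
#' @export
config_model <- function(config) {
  stopifnot(inherits(config, "bed_config"))
  build_bed_model(config_parameters(config), config_initial_stocks(config),
                  config$lookups,
                  scenario = config$active_scenario,
                  policy = config$active_policy)
}

#' Read / write a configuration as YAML
#'
#' Lookup tables are serialized as lists of `[x, y]` points. Unknown
#' keys anywhere in the document are rejected with the offending key
#' path.
#'
#' @param path File path.
#' @return `read_bed_config` returns a validated [bed_config()];
#'   `write_bed_config` returns `path` invisibly.
#' @export
read_bed_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  check_keys(doc, c("parameters", "initial_stocks", "lookups", "scenarios",
                    "policies", "simulation", "synthesis"), "config")
  for (key in c("parameters", "initial_stocks", "lookups")) {
    if (is.null(doc[[key]])) {
      stop("config is missing required section '", key, "'", call. = FALSE)
    }
  }
  bed_config(parameters = doc$parameters,
             initial_stocks = doc$initial_stocks,
             lookups = doc$lookups,
             scenarios = doc$scenarios %||% default_scenario_presets(),
             policies = doc$policies %||% list(start_year = 2020),
             simulation = doc$simulation %||%
               list(start_time = 2015, stop_time = 2035,
                    dt = 1 / 12, saveper = 1 / 12),
             synthesis = doc$synthesis)
}

config_to_list <- function(config) {
  lk <- lapply(config$lookups[c("F1", "F2", "F3", "F4")], function(tbl) {
    list(points = mapply(function(x, y) c(x, y), tbl$x, tbl$y,
                         SIMPLIFY = FALSE))
  })
  drop_null <- function(x) x[!vapply(x, is.null, TRUE)]
  list(parameters = config$parameters,
       initial_stocks = config$initial_stocks,
       lookups = lk,
       scenarios = lapply(config$scenarios, drop_null),
       policies = config$policies,
       simulation = config$simulation,
       synthesis = config$synthesis)
}

#' @rdname read_bed_config
#' @param config A [bed_config()].
#' @export
write_bed_config <- function(config, path) {
  stopifnot(inherits(config, "bed_config"))
  doc <- config_to_list(config)
  doc <- doc[!vapply(doc, is.null, TRUE)]
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' Content digest of a configuration
#'
#' MD5 of the canonical (recursively key-sorted) JSON rendering, so the
#' digest is stable under key reordering and across write/read
#' round-trips.
#'
#' @param config A [bed_config()].
#' @return Hex digest string.
#' @export
config_digest <- function(config) {
  stopifnot(inherits(config, "bed_config"))
  sort_rec <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x)) && any(nzchar(names(x)))) {
        x <- x[order(names(x))]
      }
      return(lapply(x, sort_rec))
    }
    # round to 12 significant digits so the digest survives faithful
    # serialization round-trips as well as key reordering
    if (is.numeric(x)) return(signif(x, 12))
    x
  }
  canon <- jsonlite::toJSON(sort_rec(config_to_list(config)),
                            auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(canon), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.bed_config <- function(x, ...) {
  cat("<bed_config>\n")
  cat("  parameters:", paste(names(x$parameters), unlist(x$parameters),
                             sep = "=", collapse = ", "), "\n")
  cat("  initial stocks:", paste(names(x$initial_stocks),
                                 unlist(x$initial_stocks),
                                 sep = "=", collapse = ", "), "\n")
  cat("  horizon: [", x$simulation$start_time, ",", x$simulation$stop_time,
      "] dt =", format(x$simulation$dt), "\n")
  if (!is.null(x$active_scenario)) {
    cat("  active scenario:", x$active_scenario$id, "\n")
  }
  if (!is.null(x$active_policy)) {
    cat("  active policy:", x$active_policy$id, "\n")
  }
  invisible(x)
}
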