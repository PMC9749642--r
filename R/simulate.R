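#' Simulation settings
#'
#' Fixed-step explicit Euler settings. `dt` is the integration step and
#' `saveper` the output sampling interval; both in years. `saveper` must
#' be an integer multiple of `dt` and must divide the horizon (checked
#' with relative tolerance 1e-9).
#'
#' @param start_time,stop_time Simulation horizon in calendar years.
#' @param dt Integration step (years), > 0.
#' @param saveper Output interval (years); defaults to `dt`.
#' @return A `simulation_settings` object.
#' @export
simulation_settings <- function(start_time = 2015, stop_time = 2035,
                                dt = 1 / 12, saveper = dt) {
  stopifnot(is.numeric(start_time), is.numeric(stop_time),
            is.numeric(dt), is.numeric(saveper))
  if (!(dt > 0)) stop("dt must be > 0", call. = FALSE)
  if (!(start_time < stop_time)) {
    stop("start_time must be < stop_time", call. = FALSE)
  }
  near_integer <- function(r) abs(r - round(r)) <= 1e-9 * max(1, abs(r))
  if (!near_integer(saveper / dt)) {
    stop("saveper must be an integer multiple of dt", call. = FALSE)
  }
  if (!near_integer((stop_time - start_time) / dt) ||
      !near_integer((stop_time - start_time) / saveper)) {
    stop("dt and saveper must divide the simulation horizon", call. = FALSE)
  }
  structure(list(start_time = start_time, stop_time = stop_time,
                 dt = dt, saveper = saveper),
            class = "simulation_settings")
}

# ---- equation rewriting -----------------------------------------------------

# Rewrites an equation for compiled evaluation:
#   a / b          -> .sd_div(a, b, "<var>")   (guarded division)
#   RAMP(s, t0)    -> s * MAX(0, TIME - t0)
#   STEP(h, t0)    -> IF_THEN_ELSE(TIME >= t0, h, 0)
rewrite_expr <- function(expr, var) {
  if (is.numeric(expr) || is.symbol(expr)) return(expr)
  if (is.call(expr)) {
    head <- as.character(expr[[1L]])
    args <- lapply(as.list(expr)[-1L], rewrite_expr, var = var)
    if (head == "/" && length(args) == 2L) {
      return(as.call(c(quote(.sd_div), args, var)))
    }
    if (head == "RAMP" && length(args) == 2L) {
      return(bquote(.(args[[1L]]) * MAX(0, TIME - .(args[[2L]]))))
    }
    if (head == "STEP" && length(args) == 2L) {
      return(bquote(IF_THEN_ELSE(TIME >= .(args[[2L]]), .(args[[1L]]), 0)))
    }
    if (head == "(") return(args[[1L]])
    return(as.call(c(expr[[1L]], args)))
  }
  expr
}

# ---- model compilation ------------------------------------------------------

# Compiles a validated model into a single bytecompiled step function
#   f(TIME, <stock1>, <stock2>, ...) -> list(v = <all saved values>,
#                                            d = <stock net-flow rates>)
# Parameters and lookup closures live in the function's environment.
compile_model <- function(spec, diagnostics = NULL) {
  diag <- diagnostics %||% validate_model(spec)
  if (length(diag$defects)) {
    stop("model has defects:\n", paste0("  - ", diag$defects, collapse = "\n"),
         call. = FALSE)
  }
  kinds <- vapply(spec, `[[`, "", "kind")
  nm <- names(spec)
  stock_names <- nm[kinds == "stock"]
  saved_names <- nm[kinds != "lookup"]

  E <- new.env(parent = baseenv())
  E$IF_THEN_ELSE <- function(cond, yes, no) if (cond) yes else no
  E$MAX <- function(a, b) if (a >= b) a else b
  E$MIN <- function(a, b) if (a <= b) a else b
  E$.sd_divwarned <- character()
  E$.sd_div <- function(num, den, var) {
    if (den == 0) {
      if (!var %in% E$.sd_divwarned) {
        E$.sd_divwarned <- c(E$.sd_divwarned, var)
        warning("division by zero in '", var, "'; value set to 0",
                call. = FALSE)
      }
      return(0)
    }
    num / den
  }
  for (v in spec) {
    if (v$kind == "parameter") E[[v$name]] <- v$value
    if (v$kind == "lookup") E[[v$name]] <- make_lookup_fun(v$table)
  }

  stmts <- list()
  for (v in diag$order) {
    stmts[[length(stmts) + 1L]] <-
      call("<-", as.symbol(v), rewrite_expr(spec[[v]]$equation, v))
  }
  vals_call <- as.call(c(quote(c), lapply(saved_names, as.symbol)))
  stmts[[length(stmts) + 1L]] <- call("<-", quote(.sd_v), vals_call)
  d_exprs <- lapply(stock_names, function(s) {
    terms <- NULL
    for (f in spec[[s]]$inflows) {
      terms <- if (is.null(terms)) as.symbol(f) else
        call("+", terms, as.symbol(f))
    }
    for (f in spec[[s]]$outflows) {
      terms <- if (is.null(terms)) call("-", as.symbol(f)) else
        call("-", terms, as.symbol(f))
    }
    terms %||% 0
  })
  stmts[[length(stmts) + 1L]] <-
    call("<-", quote(.sd_d), as.call(c(quote(c), d_exprs)))
  stmts[[length(stmts) + 1L]] <- quote(list(v = .sd_v, d = .sd_d))
  body <- as.call(c(quote(`{`), stmts))

  args <- setNames(rep(list(quote(expr = )), 1L + length(stock_names)),
                   c("TIME", stock_names))
  fn <- eval(call("function", as.pairlist(args), body), E)
  fn <- compiler::cmpfun(fn)
  list(fn = fn, stock_names = stock_names, saved_names = saved_names,
       initials = vapply(stock_names, function(s) spec[[s]]$initial, 0),
       env = E)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_finite <- function(res, saved_names, stock_names, t) {
  if (all(is.finite(res$v)) && all(is.finite(res$d))) return(invisible())
  bad <- unique(c(saved_names[!is.finite(res$v)],
                  stock_names[!is.finite(res$d)]))
  stop("non-finite value for '", paste(bad, collapse = "', '"),
       "' at t = ", format(t), call. = FALSE)
}

#' Advance a model by one Euler step
#'
#' Evaluates auxiliaries and flows at time `t` in dependency order, then
#' updates every stock by `stock + dt * (inflows - outflows)`.
#'
#' @param spec A validated [sd_model()].
#' @param stocks Named numeric vector of current stock values; defaults
#'   to the model initials.
#' @param t Current time (years).
#' @param dt Step size (years), > 0.
#' @return Named numeric vector of next stock values.
#' @export
sd_step <- function(spec, stocks = NULL, t, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !(dt > 0)) {
    stop("dt must be a single value > 0", call. = FALSE)
  }
  cm <- compile_model(spec)
  x <- cm$initials
  if (!is.null(stocks)) {
    if (is.null(names(stocks)) || !all(names(stocks) %in% cm$stock_names)) {
      stop("stocks must be named after the model's stock variables",
           call. = FALSE)
    }
    x[names(stocks)] <- stocks
  }
  res <- do.call(cm$fn, c(list(TIME = t), as.list(x)))
  check_finite(res, cm$saved_names, cm$stock_names, t)
  setNames(x + dt * res$d, cm$stock_names)
}

#' Run a deterministic stock-flow simulation
#'
#' Repeated explicit Euler steps from `start_time` to `stop_time`,
#' saving every model variable (stocks, flows, auxiliaries, parameters)
#' every `saveper` years. The run is a pure function of the model and
#' settings: repeated calls are bit-identical.
#'
#' @param spec A [sd_model()]; must validate cleanly.
#' @param settings A [simulation_settings()].
#' @return An object of class `sd_run`: list with `times` (saved time
#'   points) and `values` (matrix, one column per variable).
#' @export
sd_simulate <- function(spec, settings) {
  if (!inherits(settings, "simulation_settings")) {
    settings <- do.call(simulation_settings, as.list(settings))
  }
  simulate_compiled(compile_model(spec), settings)
}

# Core Euler loop over an already compiled model; used by sd_simulate()
# and by the lookup-recovery optimizer, which swaps lookup closures in
# the compiled environment between candidate evaluations.
simulate_compiled <- function(cm, settings) {
  if (!inherits(settings, "simulation_settings")) {
    settings <- do.call(simulation_settings, as.list(settings))
  }
  cm$env$.sd_divwarned <- character()
  dt <- settings$dt
  n_steps <- as.integer(round((settings$stop_time - settings$start_time) / dt))
  save_every <- as.integer(round(settings$saveper / dt))
  n_saves <- n_steps %/% save_every
  times <- settings$start_time + (0:n_saves) * settings$saveper
  out <- matrix(NA_real_, nrow = n_saves + 1L, ncol = length(cm$saved_names),
                dimnames = list(NULL, cm$saved_names))
  x <- cm$initials
  fn <- cm$fn
  t <- settings$start_time
  row <- 1L
  for (i in 0:n_steps) {
    res <- do.call(fn, c(list(TIME = t), as.list(x)))
    check_finite(res, cm$saved_names, cm$stock_names, t)
    if (i %% save_every == 0L) {
      out[row, ] <- res$v
      row <- row + 1L
    }
    if (i < n_steps) {
      x <- x + dt * res$d
      t <- settings$start_time + (i + 1L) * dt
    }
  }
  structure(list(times = times, values = out, settings = settings),
            class = "sd_run")
}

#' Extract one variable's trajectory from a run
#'
#' @param run An [sd_simulate()] result.
#' @param name Variable name.
#' @return Numeric vector, one value per saved time point.
#' @export
run_variable <- function(run, name) {
  stopifnot(inherits(run, "sd_run"))
  if (!name %in% colnames(run$values)) {
    stop("run does not contain variable '", name, "'", call. = FALSE)
  }
  run$values[, name]
}

#' @export
print.sd_run <- function(x, ...) {
  cat("<sd_run> ", length(x$times), " saved points on [",
      format(x$times[1]), ", ", format(x$times[length(x$times)]), "], ",
      ncol(x$values), " variables\n", sep = "")
  invisible(x)
}

#' @export
#' @param row.names,optional Passed through (standard S3 signature).
#' @param format `"wide"` (default; one column per variable) or `"long"`
#'   (columns `time`, `variable`, `value`).
#' @rdname sd_simulate
as.data.frame.sd_run <- function(x, row.names = NULL, optional = FALSE,
                                 format = c("wide", "long"), ...) {
  format <- match.arg(format)
  if (format == "wide") {
    return(data.frame(time = x$times, x$values, check.names = FALSE))
  }
  data.frame(
    time = rep(x$times, times = ncol(x$values)),
    variable = rep(colnames(x$values), each = length(x$times)),
    value = as.vector(x$values)
  )
}

#' Write / read a run as tidy delimited text
#'
#' Long format with columns `time,variable,value`; a leading comment
#' line records the units of the time axis. Full numeric precision is
#' kept so repeated runs produce byte-identical files.
#'
#' @param run An `sd_run`.
#' @param path Output file path.
#' @return `path`, invisibly (`read_run_result` returns a long-format
#'   data frame).
#' @export
write_run_result <- function(run, path) {
  df <- as.data.frame(run, format = "long")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time: calendar years; value: units of each model variable",
             con)
  writeLines("time,variable,value", con)
  writeLines(paste(format(df$time, digits = 17, trim = TRUE, scientific = FALSE),
                   df$variable,
                   vapply(df$value, function(v)
                     format(v, digits = 17, trim = TRUE), ""),
                   sep = ","), con)
  invisible(path)
}

#' @rdname write_run_result
#' @export
read_run_result <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
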