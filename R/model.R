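#' Model variable definitions
#'
#' A stock-flow model is a named collection of variables of five kinds:
#' * **stock** — an accumulating state, changed only by its in/out flows
#'   via Euler integration; carries an initial value.
#' * **flow** — a rate (units of its stock per year) defined by an equation.
#' * **auxiliary** — an algebraic variable computed instantaneously.
#' * **parameter** — a constant.
#' * **lookup** — a [lookup_table()] applied like a function inside
#'   equations, e.g. `F3(bed_to_patient_ratio)`.
#'
#' Equations are given as strings (or quoted R language) over other
#' variable names and a closed set of builtins: arithmetic, comparisons,
#' `IF_THEN_ELSE(cond, yes, no)`, `MAX`, `MIN`, `RAMP(slope, start)`,
#' `STEP(height, start)`, lookup application, and the reserved symbol
#' `TIME` (current simulation time in years). Nothing else is evaluated:
#' configurations are data, not code.
#'
#' @param name Variable name (a valid identifier).
#' @param equation Equation as a character string or language object
#'   (flows and auxiliaries).
#' @param initial Initial value (stocks).
#' @param inflows,outflows Character vectors naming the flow variables
#'   that increment / decrement the stock.
#' @param value Constant value (parameters).
#' @param table A [lookup_table()] (lookups).
#' @param units Free-text unit annotation.
#' @return A variable definition of class `sd_var`.
#' @name sd_vars
NULL

new_sd_var <- function(name, kind, units = "", ...) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name) ||
      make.names(name) != name) {
    stop("variable name must be a valid identifier, got: ",
         deparse(name), call. = FALSE)
  }
  structure(list(name = name, kind = kind, units = units, ...),
            class = "sd_var")
}

as_equation <- function(equation, name) {
  if (is.character(equation)) {
    expr <- tryCatch(str2lang(equation), error = function(e) {
      stop("cannot parse equation for '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  } else if (is.language(equation) || is.numeric(equation)) {
    expr <- equation
  } else {
    stop("equation for '", name, "' must be a string or language object",
         call. = FALSE)
  }
  expr
}

#' @rdname sd_vars
#' @export
sd_stock <- function(name, initial, inflows = character(),
                     outflows = character(), units = "") {
  if (!is.numeric(initial) || length(initial) != 1L) {
    stop("stock '", name, "' needs a single numeric initial value",
         call. = FALSE)
  }
  new_sd_var(name, "stock", units, initial = as.numeric(initial),
             inflows = as.character(inflows),
             outflows = as.character(outflows))
}

#' @rdname sd_vars
#' @export
sd_flow <- function(name, equation, units = "") {
  new_sd_var(name, "flow", units, equation = as_equation(equation, name))
}

#' @rdname sd_vars
#' @export
sd_aux <- function(name, equation, units = "") {
  new_sd_var(name, "auxiliary", units, equation = as_equation(equation, name))
}

#' @rdname sd_vars
#' @export
sd_param <- function(name, value, units = "") {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("parameter '", name, "' needs a single finite numeric value",
         call. = FALSE)
  }
  new_sd_var(name, "parameter", units, value = as.numeric(value))
}

#' @rdname sd_vars
#' @export
sd_lookup <- function(name, table, units = "") {
  if (!inherits(table, "lookup_table")) {
    stop("lookup '", name, "' needs a lookup_table", call. = FALSE)
  }
  table$name <- name
  new_sd_var(name, "lookup", units, table = table)
}

#' Assemble a stock-flow model
#'
#' @param ... Variable definitions created with [sd_stock()], [sd_flow()],
#'   [sd_aux()], [sd_param()], [sd_lookup()], or lists of them.
#' @return An object of class `sd_model`: a named list of variables.
#' @seealso [validate_model()], [sd_simulate()]
#' @export
sd_model <- function(...) {
  vars <- list(...)
  flat <- list()
  for (v in vars) {
    if (inherits(v, "sd_var")) {
      flat[[length(flat) + 1L]] <- v
    } else if (is.list(v)) {
      for (w in v) {
        if (!inherits(w, "sd_var")) {
          stop("sd_model() accepts sd_var objects or lists of them",
               call. = FALSE)
        }
        flat[[length(flat) + 1L]] <- w
      }
    } else {
      stop("sd_model() accepts sd_var objects or lists of them", call. = FALSE)
    }
  }
  nm <- vapply(flat, `[[`, "", "name")
  names(flat) <- nm # duplicates kept; validate_model() reports them
  structure(flat, class = "sd_model")
}

#' @export
print.sd_model <- function(x, ...) {
  kinds <- vapply(x, `[[`, "", "kind")
  cat("<sd_model> ", length(x), " variables (",
      paste(sprintf("%d %s", as.integer(table(kinds)),
                    names(table(kinds))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# ---- expression machinery ---------------------------------------------------

SD_BUILTINS <- c("+", "-", "*", "/", "(", "<", "<=", ">", ">=", "==", "!=",
                 "&&", "||", "!", "IF_THEN_ELSE", "MAX", "MIN", "RAMP", "STEP")
SD_RESERVED <- "TIME"

# All symbols referenced by an expression (excluding function heads of
# builtin calls; lookup applications contribute the lookup's name).
expr_refs <- function(expr) {
  refs <- character()
  walk <- function(e) {
    if (is.symbol(e)) {
      refs[[length(refs) + 1L]] <<- as.character(e)
    } else if (is.call(e)) {
      head <- e[[1L]]
      if (is.symbol(head)) {
        h <- as.character(head)
        if (!h %in% SD_BUILTINS) refs[[length(refs) + 1L]] <<- h
      } else {
        walk(head)
      }
      for (a in as.list(e)[-1L]) walk(a)
    }
  }
  walk(expr)
  setdiff(unique(refs), SD_RESERVED)
}

# Checks an equation against the closed builtin set. Returns character
# vector of problems (empty if clean).
check_expression <- function(expr, var, lookup_names) {
  problems <- character()
  walk <- function(e) {
    if (is.numeric(e) || is.symbol(e)) return(invisible())
    if (is.call(e)) {
      head <- e[[1L]]
      if (!is.symbol(head)) {
        problems[[length(problems) + 1L]] <<-
          paste0("'", var, "': non-symbol call head ", deparse(e))
        return(invisible())
      }
      h <- as.character(head)
      if (!(h %in% SD_BUILTINS || h %in% lookup_names)) {
        problems[[length(problems) + 1L]] <<-
          paste0("'", var, "': disallowed function '", h, "'")
      }
      for (a in as.list(e)[-1L]) walk(a)
      return(invisible())
    }
    problems[[length(problems) + 1L]] <<-
      paste0("'", var, "': disallowed element ", deparse(e))
  }
  walk(expr)
  problems
}

#' Validate a stock-flow model
#'
#' Collects structural defects rather than throwing: duplicate names,
#' undefined references, disallowed functions, stocks whose flow lists
#' point at non-flow variables, and dependency cycles among non-stock
#' variables (stocks legitimately close feedback loops; algebraic
#' variables must not). Also computes the topological evaluation order
#' for auxiliaries and flows.
#'
#' @param spec An [sd_model()].
#' @return An object of class `sd_diagnostics`: list with elements
#'   `defects` (character vector, empty iff the model is runnable) and
#'   `order` (evaluation order for auxiliaries and flows, `NULL` when a
#'   cycle prevents ordering).
#' @export
validate_model <- function(spec) {
  if (!inherits(spec, "sd_model")) {
    stop("validate_model() expects an 'sd_model'", call. = FALSE)
  }
  defects <- character()
  nm <- vapply(spec, `[[`, "", "name")
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) {
    defects <- c(defects, paste0("duplicate definition of '", dup, "'"))
  }
  kinds <- vapply(spec, `[[`, "", "kind")
  names(kinds) <- nm
  lookup_names <- nm[kinds == "lookup"]

  eq_vars <- nm[kinds %in% c("flow", "auxiliary")]
  deps <- list()
  for (v in spec) {
    if (!v$kind %in% c("flow", "auxiliary")) next
    defects <- c(defects, check_expression(v$equation, v$name, lookup_names))
    refs <- expr_refs(v$equation)
    undef <- setdiff(refs, nm)
    if (length(undef)) {
      defects <- c(defects, paste0("'", v$name, "' references undefined '",
                                   undef, "'"))
    }
    deps[[v$name]] <- intersect(refs, eq_vars)
  }
  for (v in spec) {
    if (v$kind != "stock") next
    if (!is.finite(v$initial)) {
      defects <- c(defects, paste0("stock '", v$name,
                                   "' has non-finite initial value"))
    }
    for (f in c(v$inflows, v$outflows)) {
      if (!f %in% nm) {
        defects <- c(defects, paste0("stock '", v$name,
                                     "' references undefined flow '", f, "'"))
      } else if (!kinds[[f]] %in% c("flow", "auxiliary")) {
        defects <- c(defects, paste0("stock '", v$name, "' flow '", f,
                                     "' is a ", kinds[[f]],
                                     ", not a flow/auxiliary"))
      }
    }
  }

  # Kahn's algorithm over auxiliaries + flows only.
  order <- character()
  remaining <- eq_vars
  pending <- deps
  repeat {
    ready <- remaining[vapply(remaining, function(v) {
      length(intersect(pending[[v]], remaining)) == 0L
    }, TRUE)]
    if (!length(ready)) break
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining)) {
    defects <- c(defects,
                 paste0("dependency cycle among non-stock variables: {",
                        paste(sort(remaining), collapse = ", "), "}"))
    order <- NULL
  }
  structure(list(defects = defects, order = order),
            class = "sd_diagnostics")
}

#' @export
print.sd_diagnostics <- function(x, ...) {
  if (!length(x$defects)) {
    cat("<sd_diagnostics> model is runnable (no defects)\n")
  } else {
    cat("<sd_diagnostics> ", length(x$defects), " defect(s):\n", sep = "")
    cat(paste0("  - ", x$defects, collapse = "\n"), "\n")
  }
  invisible(x)
}
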