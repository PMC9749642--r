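#' Piecewise-linear lookup table (graphical function)
#'
#' A lookup table is the standard system-dynamics device for a nonlinear,
#' empirically shaped relationship: an ordered set of `(x, y)` breakpoints
#' evaluated by linear interpolation, clamped to the endpoint `y` values
#' outside the breakpoint domain. The bed model uses four of them (the
#' "rate effects" F1--F4) to drive capacity growth from occupancy and
#' staffing ratios.
#'
#' @param x Numeric vector of breakpoint abscissae, strictly increasing,
#'   length >= 2.
#' @param y Numeric vector of breakpoint ordinates, same length as `x`.
#' @param name Identifier used in messages and when the table is applied
#'   inside model equations.
#' @return An object of class `lookup_table`.
#' @examples
#' f <- lookup_table(c(0, 1), c(0, 1))
#' lookup_eval(f, 0.5)   # 0.5
#' lookup_eval(f, -3)    # clamped to 0
#' @export
lookup_table <- function(x, y, name = "lookup") {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("lookup table '", name, "': breakpoints must be numeric", call. = FALSE)
  }
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("lookup table '", name, "': x and y must have the same length",
         call. = FALSE)
  }
  if (length(x) < 2L) {
    stop("lookup table '", name, "': at least 2 breakpoints required",
         call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("lookup table '", name, "': breakpoints must be finite", call. = FALSE)
  }
  if (any(diff(x) <= 0)) {
    stop("lookup table '", name, "': x breakpoints must be strictly increasing",
         call. = FALSE)
  }
  structure(list(name = name, x = x, y = y), class = "lookup_table")
}

#' Evaluate a lookup table
#'
#' Clamped piecewise-linear interpolation: below the first breakpoint the
#' first `y` is returned, above the last breakpoint the last `y`; between
#' breakpoints the value is linear in `x`.
#'
#' @param table A [lookup_table()].
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of interpolated values, same length as `x`.
#' @export
lookup_eval <- function(table, x) {
  if (!inherits(table, "lookup_table")) {
    stop("lookup_eval() expects a 'lookup_table'", call. = FALSE)
  }
  xs <- table$x
  ys <- table$y
  n <- length(xs)
  i <- findInterval(x, xs, all.inside = TRUE)
  w <- (x - xs[i]) / (xs[i + 1L] - xs[i])
  out <- ys[i] + w * (ys[i + 1L] - ys[i])
  out[x <= xs[1L]] <- ys[1L] # exact endpoint clamping
  out[x >= xs[n]] <- ys[n]
  out
}

# Fast scalar closure used inside compiled model steps.
make_lookup_fun <- function(table) {
  xs <- table$x
  ys <- table$y
  n <- length(xs)
  function(x) {
    if (x <= xs[1L]) return(ys[1L])
    if (x >= xs[n]) return(ys[n])
    i <- findInterval(x, xs)
    ys[i] + (ys[i + 1L] - ys[i]) * (x - xs[i]) / (xs[i + 1L] - xs[i])
  }
}

lookup_nondecreasing <- function(table) all(diff(table$y) >= 0)
lookup_nonincreasing <- function(table) all(diff(table$y) <= 0)

#' @export
print.lookup_table <- function(x, ...) {
  cat("<lookup_table> ", x$name, ": ", length(x$x), " breakpoints on [",
      format(x$x[1]), ", ", format(x$x[length(x$x)]), "]\n", sep = "")
  print(data.frame(x = x$x, y = x$y), row.names = FALSE)
  invisible(x)
}
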