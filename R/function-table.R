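# ROM-style piecewise-polynomial function tables.  The pipeline hardware
# evaluates its fixed function forms (cut-off factors, reciprocal square
# root) from read-only tables; the emulator models them as segmented
# quadratic fits accurate to single-precision-grade relative error.

#' Build a ROM-style function table
#'
#' Fits a piecewise quadratic to `f` over `[lower, upper]` using `segments`
#' intervals, each interpolating the function at its endpoints and midpoint.
#' With `spacing = "log"` the breakpoints are geometric and the local
#' variable is logarithmic, which keeps the *relative* error of power-law
#' functions flat across decades (the layout a hardware table would use for
#' r^-1 and r^-12 style kernels).
#'
#' @param f vectorized function of one variable.
#' @param lower,upper table domain; `lower > 0` required for log spacing.
#' @param segments number of segments (>= 1).
#' @param spacing `"uniform"` or `"log"`.
#' @return an object of class `function_table`.
#' @examples
#' tab <- build_function_table(function(t) exp(-t), 0, 4, segments = 256)
#' eval_table(tab, c(0, 1, 3.5))
#' @export
build_function_table <- function(f, lower, upper, segments = 4096L,
                                 spacing = c("uniform", "log")) {
  spacing <- match.arg(spacing)
  stopifnot(is.function(f), upper > lower, segments >= 1)
  if (spacing == "log" && lower <= 0) stop("log spacing requires lower > 0")
  segments <- as.integer(segments)
  if (spacing == "uniform") {
    brk <- seq(lower, upper, length.out = segments + 1L)
  } else {
    brk <- exp(seq(log(lower), log(upper), length.out = segments + 1L))
  }
  x0 <- brk[-(segments + 1L)]
  x1 <- brk[-1L]
  xm <- if (spacing == "uniform") (x0 + x1) / 2 else sqrt(x0 * x1)
  f0 <- f(x0); fm <- f(xm); f1 <- f(x1)
  if (any(!is.finite(c(f0, fm, f1)))) {
    stop("function is not finite over the table domain")
  }
  # quadratic a + b*u + c*u^2 through (0,f0), (1/2,fm), (1,f1) in the local
  # (possibly logarithmic) segment coordinate u
  cc <- 2 * f0 + 2 * f1 - 4 * fm
  bb <- f1 - f0 - cc
  structure(
    list(
      lower = lower, upper = upper, segments = segments, spacing = spacing,
      a = f0, b = bb, c = cc
    ),
    class = "function_table"
  )
}

#' @export
print.function_table <- function(x, ...) {
  cat(sprintf(
    "<function_table> %d quadratic segments, %s spacing on [%.6g, %.6g]\n",
    x$segments, x$spacing, x$lower, x$upper
  ))
  invisible(x)
}

#' Evaluate a ROM function table
#'
#' @param table a `function_table`.
#' @param t numeric vector of arguments; all must lie inside the table
#'   domain.
#' @return numeric vector of table values.
#' @export
eval_table <- function(table, t) {
  stopifnot(inherits(table, "function_table"))
  if (any(t < table$lower | t > table$upper)) {
    stop("argument outside the table domain")
  }
  if (table$spacing == "uniform") {
    s <- (t - table$lower) / (table$upper - table$lower) * table$segments
  } else {
    s <- (log(t) - log(table$lower)) /
      (log(table$upper) - log(table$lower)) * table$segments
  }
  idx <- pmin(pmax(floor(s), 0), table$segments - 1L)
  u <- s - idx
  i <- idx + 1L
  table$a[i] + table$b[i] * u + table$c[i] * u * u
}
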