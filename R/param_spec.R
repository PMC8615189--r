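#' Parameter specification for truncated log-normal sampling
#'
#' A `param_spec` describes one Monte Carlo input: its arithmetic mean and
#' standard deviation, truncation limits, an optional squared correlation
#' with body weight, and a unit annotation. Sampling draws from the
#' log-normal whose untruncated arithmetic moments match `mean`/`sd` and
#' rejects draws outside `[lower, upper]` (see
#' [sample_truncated_lognormal()]).
#'
#' @param mean Arithmetic mean, in the units of the parameter. Must be
#'   positive unless `sd == 0`.
#' @param sd Arithmetic standard deviation, same units. `sd = 0` denotes a
#'   degenerate (constant) parameter.
#' @param lower,upper Truncation bounds. `upper` may be `Inf` (unbounded).
#' @param r2_weight Optional squared correlation with body weight, in
#'   `[0, 1]`. `NULL` when the parameter is not weight-correlated.
#' @param unit Unit annotation (e.g. `"L/kg"`, `"mL/min"`); kept as a string
#'   and validated against the expected unit when a scenario file is loaded.
#' @param name Optional label used in validation error messages.
#' @return An object of class `param_spec`.
#' @examples
#' param_spec(84.1, 18.9, lower = 40, unit = "kg", name = "weight")
#' @export
param_spec <- function(mean, sd, lower = 0, upper = Inf, r2_weight = NULL,
                       unit = NULL, name = NULL) {
  spec <- structure(
    list(mean = as.numeric(mean), sd = as.numeric(sd),
         lower = as.numeric(lower), upper = as.numeric(upper),
         r2_weight = if (is.null(r2_weight)) NULL else as.numeric(r2_weight),
         unit = unit, name = name),
    class = "param_spec")
  validate_param_spec(spec)
  spec
}

#' Validate a parameter specification
#'
#' Checks the `param_spec` invariants: `sd >= 0`, `lower < upper`, `mean`
#' inside the truncation interval, `r2_weight` in `[0, 1]`. Errors name the
#' offending field.
#'
#' @param spec A [param_spec()].
#' @return `spec`, invisibly, if valid.
#' @export
validate_param_spec <- function(spec) {
  lbl <- if (is.null(spec$name)) "param_spec" else spec$name
  fail <- function(field, msg) {
    stop(sprintf("%s$%s: %s", lbl, field, msg), call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  if (!num1(spec$mean)) fail("mean", "must be a single non-missing number")
  if (!num1(spec$sd)) fail("sd", "must be a single non-missing number")
  if (spec$sd < 0) fail("sd", "must be >= 0")
  if (spec$sd > 0 && spec$mean <= 0)
    fail("mean", "must be > 0 for log-normal sampling")
  if (!num1(spec$lower)) fail("lower", "must be a single number")
  if (!(num1(spec$upper) || is.infinite(spec$upper)))
    fail("upper", "must be a single number or Inf")
  if (!(spec$lower < spec$upper))
    fail("lower", sprintf("lower (%g) must be < upper (%g)",
                          spec$lower, spec$upper))
  if (spec$mean < spec$lower || spec$mean > spec$upper)
    fail("mean", sprintf("mean (%g) must lie within [%g, %g]",
                         spec$mean, spec$lower, spec$upper))
  if (!is.null(spec$r2_weight)) {
    if (!num1(spec$r2_weight) || spec$r2_weight < 0 || spec$r2_weight > 1)
      fail("r2_weight", "must be in [0, 1]")
  }
  invisible(spec)
}

#' @export
print.param_spec <- function(x, ...) {
  up <- if (is.infinite(x$upper)) "Inf" else format(x$upper)
  cat(sprintf("<param_spec%s> %g +/- %g (%g-%s)%s%s\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$mean, x$sd, x$lower, up,
              if (is.null(x$unit)) "" else paste0(" ", x$unit),
              if (is.null(x$r2_weight)) ""
              else sprintf(", r2(weight) = %g", x$r2_weight)))
  invisible(x)
}
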