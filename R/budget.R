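#' Biomass budgets
#'
#' The total biomass function `M(t)` prescribes, independently of the
#' populations, the total amount of biomass available to the ecosystem
#' (abiotic reserve plus trophically allocated biomass).  It must be
#' positive and continuously differentiable over the analysis window,
#' and the framework's standing assumption is
#' \eqn{M(t) \ge \sum_i \tau_i(t)} (checked, and violations flagged, by
#' [flux_series()]).
#'
#' `biomass_budget()` wraps arbitrary functions; when `dM_dt` is omitted
#' a central-difference fallback with step `1e-6 * (1 + t)` is used and
#' flagged.  Convenience constructors cover the constant, linear and
#' sinusoidal shapes used by the fixtures.
#'
#' @param M function `t -> total biomass` (vectorized).
#' @param dM_dt optional analytic derivative.
#' @param label provenance tag.
#' @return an object of class `biomass_budget` with fields `M`,
#'   `dM_dt`, `fd_fallback`, `label`.
#' @export
biomass_budget <- function(M, dM_dt = NULL, label = "custom") {
  stopifnot(is.function(M))
  fd <- is.null(dM_dt)
  if (fd) {
    dM_dt <- function(t) {
      h <- 1e-6 * (1 + abs(t))
      (M(t + h) - M(t - h)) / (2 * h)
    }
  }
  structure(list(M = M, dM_dt = dM_dt, fd_fallback = fd, label = label),
            class = "biomass_budget")
}

#' @rdname biomass_budget
#' @param value constant total biomass, `> 0`.
#' @export
constant_budget <- function(value) {
  if (value <= 0) stop_domain("total biomass must be positive")
  biomass_budget(function(t) rep_len(value, length(t)),
                 function(t) rep_len(0, length(t)),
                 label = sprintf("constant(%g)", value))
}

#' @rdname biomass_budget
#' @param m0 intercept; `slope` per-time drift.
#' @param slope linear drift rate.
#' @export
linear_budget <- function(m0, slope) {
  biomass_budget(function(t) m0 + slope * t,
                 function(t) rep_len(slope, length(t)),
                 label = sprintf("linear(%g,%g)", m0, slope))
}

#' @rdname biomass_budget
#' @param amplitude,period,phase sinusoidal modulation parameters.
#' @export
sinusoidal_budget <- function(m0, amplitude, period, phase = 0) {
  om <- 2 * pi / period
  biomass_budget(function(t) m0 + amplitude * sin(om * t + phase),
                 function(t) amplitude * om * cos(om * t + phase),
                 label = sprintf("sinusoidal(%g,%g,%g)", m0, amplitude, period))
}

#' @export
print.biomass_budget <- function(x, ...) {
  cat(sprintf("<biomass_budget> %s%s\n", x$label,
              if (x$fd_fallback) " (finite-difference dM/dt)" else ""))
  invisible(x)
}

# Budget from a declarative spec.  `expression` kind evaluates a text
# expression in `t` (single-variable, base math only).
build_budget <- function(spec) {
  switch(spec$kind %||% stop_domain("budget spec needs a `kind`"),
         constant = constant_budget(spec$value %||% 1),
         linear = linear_budget(spec$m0 %||% 1, spec$slope %||% 0),
         sinusoidal = sinusoidal_budget(spec$m0 %||% 1,
                                        spec$amplitude %||% 0.1,
                                        spec$period %||% 1,
                                        spec$phase %||% 0),
         expression = {
           expr <- parse(text = spec$text)[[1L]]
           biomass_budget(function(t) eval(expr, list(t = t), baseenv()),
                          label = paste0("expression(", spec$text, ")"))
         },
         stop_domain("unknown budget kind '%s'", spec$kind))
}
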