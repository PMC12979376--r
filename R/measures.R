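#' Memory measures for trophic functionals
#'
#' A memory measure is the family \eqn{\mu_t} of positive measures on
#' `[0, t]` that weights a species' past states in its trophic
#' functional.  Two kinds are supported: absolutely continuous measures
#' given by a density `w(t, s)` (history matters -- "memory"), and the
#' memory-free Dirac point mass \eqn{\mu_t = t\,\delta(t - s)}, under
#' which only the present state contributes.
#'
#' `gaussian_measure(a)` builds the Gaussian-type density
#' \eqn{w_t(s) = e^{-a (s - t)^2}} with analytic time derivative
#' \eqn{\partial w_t/\partial t = -2 a (t - s) w_t(s)}; `a = 0` is the
#' flat (uniform-history) limiting kernel.  `dirac_measure()` builds the
#' memory-free measure.  `density_measure()` wraps a user kernel; when
#' `dw_dt` is omitted it falls back to central finite differences with
#' step `1e-6 * (1 + t)` and flags the fallback.
#'
#' @param a nonnegative Gaussian width parameter (inverse squared time).
#' @return an object of class `memory_measure` with fields `kind`
#'   (`"density"` or `"dirac"`), and for densities `w(t, s)`,
#'   `dw_dt(t, s)` (both vectorized over `s`), `params`, and
#'   `fd_fallback`.
#' @examples
#' mu <- gaussian_measure(1)
#' mu$w(1, 0)        # exp(-1)
#' mu$dw_dt(1, 0)    # -2 * exp(-1)
#' @export
gaussian_measure <- function(a) {
  if (!is.finite(a) || a < 0) stop_domain("Gaussian width `a` must be >= 0")
  force(a)
  structure(list(
    kind = "density",
    w = function(t, s) exp(-a * (s - t)^2),
    dw_dt = function(t, s) -2 * a * (t - s) * exp(-a * (s - t)^2),
    params = list(family = "gaussian", a = a),
    fd_fallback = FALSE
  ), class = "memory_measure")
}

#' @rdname gaussian_measure
#' @export
dirac_measure <- function() {
  structure(list(kind = "dirac", params = list(family = "dirac")),
            class = "memory_measure")
}

#' @rdname gaussian_measure
#' @param w density function `(t, s) -> weight`, nonnegative for
#'   `0 <= s <= t` with `w(t, t) > 0`.
#' @param dw_dt optional analytic partial derivative of `w` in `t`.
#' @export
density_measure <- function(w, dw_dt = NULL) {
  stopifnot(is.function(w))
  fd <- is.null(dw_dt)
  if (fd) {
    dw_dt <- function(t, s) {
      h <- 1e-6 * (1 + abs(t))
      (w(t + h, s) - w(t - h, s)) / (2 * h)
    }
  }
  structure(list(kind = "density", w = w, dw_dt = dw_dt,
                 params = list(family = "custom"), fd_fallback = fd),
            class = "memory_measure")
}

#' @export
print.memory_measure <- function(x, ...) {
  cat(sprintf("<memory_measure> kind=%s family=%s%s\n", x$kind,
              x$params$family,
              if (isTRUE(x$fd_fallback)) " (finite-difference dw/dt)" else ""))
  invisible(x)
}

# Build a measure from its declarative JSON/config spec.
build_measure <- function(spec) {
  switch(spec$kind %||% stop_domain("measure spec needs a `kind`"),
         gaussian = gaussian_measure(spec$a %||% 1),
         dirac = dirac_measure(),
         stop_domain("unknown measure kind '%s'", spec$kind))
}
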