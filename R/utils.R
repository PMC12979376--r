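# Small numerical helpers shared across modules.

#' Composite trapezoid integral
#'
#' @param x strictly increasing abscissae.
#' @param y ordinates (same length as `x`).
#' @return the scalar integral of the piecewise-linear interpolant.
#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  m <- length(x)
  if (m < 2L) return(0)
  sum(diff(x) * (y[-m] + y[-1L]) / 2)
}

# Running trapezoid integral; first element is 0.
cum_trapz <- function(x, y) {
  m <- length(x)
  if (m < 2L) return(numeric(m))
  c(0, cumsum(diff(x) * (y[-m] + y[-1L]) / 2))
}

# Central-difference derivative on a (possibly non-uniform) grid, one-sided
# at the ends.  Used where an analytic derivative is unavailable.
grid_gradient <- function(x, y) {
  m <- length(x)
  if (m < 2L) return(rep(NA_real_, m))
  d <- numeric(m)
  d[1L] <- (y[2L] - y[1L]) / (x[2L] - x[1L])
  d[m] <- (y[m] - y[m - 1L]) / (x[m] - x[m - 1L])
  if (m > 2L) {
    i <- 2:(m - 1L)
    d[i] <- (y[i + 1L] - y[i - 1L]) / (x[i + 1L] - x[i - 1L])
  }
  d
}

# Sign with a deadband: |x| <= eps counts as zero.
sign_deadband <- function(x, eps) {
  s <- sign(x)
  s[abs(x) <= eps] <- 0
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) {
  stop(structure(class = c("glvflux_domain_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1L))))
}
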