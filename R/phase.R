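# Planar phase-portrait tooling: Poincare period detection, orbit
# classification, and cycle time-averages.

# Same-direction crossings of the section {N1 = anchor1, N2 > anchor2}.
# Crossing times refined by linear interpolation between bracketing grid
# points.  Returns times and interpolated states.
poincare_crossings <- function(trajectory, anchor) {
  tt <- trajectory$t
  N1 <- trajectory$N[, 1L]
  N2 <- trajectory$N[, 2L]
  g <- N1 - anchor[1L]
  k <- which(g[-length(g)] * g[-1L] < 0)  # strict sign changes
  if (!length(k)) return(NULL)
  frac <- g[k] / (g[k] - g[k + 1L])
  t_cross <- tt[k] + frac * (tt[k + 1L] - tt[k])
  N2_cross <- N2[k] + frac * (N2[k + 1L] - N2[k])
  dir <- sign(g[k + 1L] - g[k])
  upper <- N2_cross > anchor[2L]
  if (!any(upper)) return(NULL)
  dir0 <- dir[which(upper)[1L]]  # fix the crossing direction
  keep <- upper & dir == dir0
  list(t = t_cross[keep], N2 = N2_cross[keep],
       N1 = rep(anchor[1L], sum(keep)))
}

#' Detect the orbit period via a Poincare section
#'
#' Places the section on the vertical line `N1 = anchor1` restricted to
#' `N2 > anchor2` (the anchor is normally the interior equilibrium),
#' records same-direction crossings with sub-grid linear interpolation,
#' and returns the time between successive crossings.  Returns `NULL`
#' when fewer than two crossings occur, or when the state-space gap
#' between successive returns exceeds `gap_tol` times the orbit
#' diameter (an open, non-returning orbit).
#'
#' @param trajectory a two-species `glv_trajectory`.
#' @param anchor length-2 section center (interior equilibrium).
#' @param gap_tol closed-orbit acceptance threshold as a fraction of the
#'   orbit diameter (default 1%).
#' @return the period (median of successive crossing intervals), or
#'   `NULL`; when present, attributes `first_crossing` and `return_gap`
#'   are attached.
#' @export
detect_period <- function(trajectory, anchor, gap_tol = 0.01) {
  stopifnot(inherits(trajectory, "glv_trajectory"))
  if (trajectory$model$n != 2L) stop_domain("period detection requires n = 2")
  cr <- poincare_crossings(trajectory, anchor)
  if (is.null(cr) || length(cr$t) < 2L) return(NULL)
  gap <- abs(cr$N2[2L] - cr$N2[1L])
  diam <- sqrt(diff(range(trajectory$N[, 1L]))^2 +
               diff(range(trajectory$N[, 2L]))^2)
  if (diam > 0 && gap > gap_tol * diam) return(NULL)
  period <- stats::median(diff(cr$t))
  attr(period, "first_crossing") <- cr$t[1L]
  attr(period, "return_gap") <- gap
  period
}

#' Time-average of the populations over one orbit period
#'
#' Computes \eqn{(1/T)\int N(t)\,dt} over exactly one period by the
#' trapezoid rule, with log-linearly interpolated endpoint states.  For
#' a closed orbit this average is independent of the starting phase; on
#' a zero-diagonal two-species LV cycle it equals the coexistence
#' equilibrium (the classical time-average property).
#'
#' @param trajectory a `glv_trajectory`.
#' @param period the orbit period (from [detect_period()]).
#' @param t_start start of the averaging window (default: the first
#'   crossing recorded on `period`, else the trajectory start).
#' @return named abundance vector of cycle means.
#' @export
cycle_average <- function(trajectory, period, t_start = NULL) {
  stopifnot(inherits(trajectory, "glv_trajectory"))
  if (is.null(period) || !is.finite(period) || period <= 0)
    stop_domain("`period` must be a positive number")
  if (is.null(t_start))
    t_start <- attr(period, "first_crossing") %||% trajectory$t[1L]
  t_stop <- t_start + as.numeric(period)
  tt <- trajectory$t
  if (t_stop > tt[length(tt)] + 1e-9 * (1 + t_stop))
    stop_domain("trajectory span too short: need [%g, %g]", t_start, t_stop)
  inner <- which(tt > t_start & tt < t_stop)
  s <- c(t_start, tt[inner], t_stop)
  Ns <- rbind(state_at(trajectory, t_start)$N,
              trajectory$N[inner, , drop = FALSE],
              state_at(trajectory, t_stop)$N)
  avg <- apply(Ns, 2L, function(y) trapz(s, y)) / as.numeric(period)
  stats::setNames(avg, trajectory$model$labels)
}

#' Classify a planar orbit
#'
#' Combines period detection, escape detection and fixed-point
#' detection into a single report:
#' \itemize{
#'   \item `fixed-point`: orbit diameter below `1e-8` relative to scale;
#'   \item `open/escaping`: any abundance exceeding `escape_factor`
#'     times its initial value or underflowing `positivity_floor`;
#'   \item `closed`: a period was detected with an acceptable return
#'     gap; otherwise `open/escaping`.
#' }
#'
#' @param trajectory a two-species `glv_trajectory`.
#' @param equilibrium length-2 interior equilibrium (Poincare anchor).
#' @param escape_factor growth factor counting as escape (default 1e6).
#' @param positivity_floor abundance underflow threshold (default 1e-12).
#' @return an object of class `orbit_report`: `classification`
#'   (`"closed"`, `"open/escaping"`, `"fixed-point"`), `period`,
#'   `cycle_average`, `return_gap` (NULL where not applicable).
#' @export
classify_orbit <- function(trajectory, equilibrium,
                           escape_factor = 1e6, positivity_floor = 1e-12) {
  stopifnot(inherits(trajectory, "glv_trajectory"))
  if (trajectory$model$n != 2L) stop_domain("orbit classification requires n = 2")
  N <- trajectory$N
  scale <- pmax(abs(trajectory$N0), .Machine$double.xmin)
  diam <- max(apply(N, 2L, function(x) diff(range(x)) / max(abs(x))))
  if (diam < 1e-8)
    return(structure(list(classification = "fixed-point", period = NULL,
                          cycle_average = NULL, return_gap = NULL),
                     class = "orbit_report"))
  escaped <- any(t(N) > escape_factor * scale) || any(N < positivity_floor)
  if (escaped)
    return(structure(list(classification = "open/escaping", period = NULL,
                          cycle_average = NULL, return_gap = NULL),
                     class = "orbit_report"))
  period <- detect_period(trajectory, equilibrium)
  if (is.null(period))
    return(structure(list(classification = "open/escaping", period = NULL,
                          cycle_average = NULL, return_gap = NULL),
                     class = "orbit_report"))
  avg <- cycle_average(trajectory, period)
  structure(list(classification = "closed", period = as.numeric(period),
                 cycle_average = avg,
                 return_gap = attr(period, "return_gap")),
            class = "orbit_report")
}

#' @export
print.orbit_report <- function(x, ...) {
  cat(sprintf("<orbit_report> %s", x$classification))
  if (!is.null(x$period))
    cat(sprintf(", period %.6g, cycle average (%s)", x$period,
                paste(format(x$cycle_average, digits = 6), collapse = ", ")))
  cat("\n")
  invisible(x)
}
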