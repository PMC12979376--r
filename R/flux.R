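# The biomass budget in motion: abiotic reservoir R = M - sum(tau),
# flux functional Y = dM/dt - dR/dt = sum d tau_i/dt, and the sign-
# scenario taxonomy of the energy flow.

#' Abiotic reservoir series
#'
#' `R(t) = M(t) - sum_i tau_i(t)`: the fraction of total biomass not
#' allocated to biological activity.  Negative values breach the
#' standing budget assumption; they are returned but flagged.
#'
#' @param budget a [biomass_budget()].
#' @param tau a `trophic_series` (see [trophic_series()]).
#' @return list with `t`, `R`, and logical `violation` per grid point.
#' @export
reservoir_series <- function(budget, tau) {
  stopifnot(inherits(budget, "biomass_budget"),
            inherits(tau, "trophic_series"))
  M <- budget$M(tau$t)
  R <- M - rowSums(tau$tau)
  list(t = tau$t, R = R, violation = R < 0)
}

#' Full flux series: reservoir, biomass derivative, and flux functional
#'
#' Assembles the complete biomass budget along a trajectory: the trophic
#' series `tau` and `dtau_dt`, the reservoir `R = M - sum(tau)` (exact
#' by construction), `Mp = dM/dt`, `Rp = Mp - sum(dtau_dt)`, and the
#' flux functional `Y` computed by two independent routes -- the force
#' sum `Y_sum = sum_i dtau_i/dt` and the continuity route
#' `Y_budget = d/dt [M - R]` by central finite differences of the
#' `M - R` series.  The two must agree up to quadrature/differencing
#' error; their maximum discrepancy is stored.  Each time point also
#' receives a sign-scenario label (see [classify_scenarios()]).
#'
#' @inheritParams trophic_functional
#' @param budget a [biomass_budget()].
#' @param eps deadband for scenario signs, passed to
#'   [classify_scenarios()]; `NULL` for the scale-free default.
#' @return an object of class `flux_series`: list with `t`, `tau`,
#'   `dtau_dt`, `M`, `Mp`, `R`, `Rp`, `Y_sum`, `Y_budget`,
#'   `discrepancy`, `budget_violation`, `scenario`, `measure_kind`,
#'   `max_abs_N`.
#' @export
flux_series <- function(trajectory, weights, measure, budget, eps = NULL) {
  stopifnot(inherits(budget, "biomass_budget"))
  ts <- trophic_series(trajectory, weights, measure)
  M <- budget$M(ts$t)
  Mp <- budget$dM_dt(ts$t)
  tau_sum <- rowSums(ts$tau)
  R <- M - tau_sum
  Y_sum <- rowSums(ts$dtau_dt)
  Rp <- Mp - Y_sum
  # continuity route: d/dt [M - R] = d/dt sum(tau), by finite differences
  Y_budget <- grid_gradient(ts$t, tau_sum)
  fl <- structure(list(t = ts$t, tau = ts$tau, dtau_dt = ts$dtau_dt,
                       M = M, Mp = Mp, R = R, Rp = Rp,
                       Y_sum = Y_sum, Y_budget = Y_budget,
                       discrepancy = max(abs(Y_sum - Y_budget)),
                       budget_violation = R < 0,
                       measure_kind = ts$measure_kind,
                       max_abs_N = max(abs(trajectory$N))),
                  class = "flux_series")
  fl$scenario <- classify_scenarios(fl, eps = eps)
  fl
}

#' @export
print.flux_series <- function(x, ...) {
  cat(sprintf("<flux_series> %d points, measure=%s, sup|Y|=%.3g, route discrepancy=%.3g\n",
              length(x$t), x$measure_kind, max(abs(x$Y_sum)), x$discrepancy))
  cat("scenarios:", paste(names(table(x$scenario)), table(x$scenario),
                          sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Sign-scenario classification of the energy flow
#'
#' Labels every time point by the sign triple of `(Y, M', R')` under a
#' deadband (values with `|x| <= eps` count as zero):
#' \itemize{
#'   \item `Y > 0`: energy enters the biological subsystem (endothermic
#'     regime).  `a`: populations and reservoir both grow; `b`: the
#'     reservoir is drawn down to fuel population growth; `c`: reservoir
#'     depletion releases energy outward while populations still grow.
#'   \item `Y < 0`: the biological subsystem loses biomass.  `d`:
#'     external input and population decline both feed the reservoir;
#'     `e`: population decline feeds the reservoir and releases energy
#'     (exothermic); `f`: populations and reservoir are depleted
#'     together.
#'   \item `Y = 0`: steady populations.  `g`: all incoming energy
#'     enhances the reservoir; `h`: the reservoir drains outward;
#'     `"null"`: full standstill.
#' }
#' Sign triples not in the taxonomy (arithmetically impossible given
#' `Y = M' - R'` outside the deadband) are labeled `"mixed"`.
#'
#' @param flux a `flux_series`.
#' @param eps nonnegative deadband; the default is `1e-9` times the
#'   larger of the flux magnitudes and the biomass turnover scale
#'   `max|sum(tau)| / span`, so that a flux that is pure cancellation
#'   noise (the conservation regime) reads as zero rather than as sign
#'   noise.
#' @return character vector of labels, one per time point.
#' @export
classify_scenarios <- function(flux, eps = NULL) {
  stopifnot(inherits(flux, "flux_series"))
  if (is.null(eps)) {
    turnover <- if (!is.null(flux$tau))
      max(abs(rowSums(flux$tau))) / max(diff(range(flux$t)), 1e-300) else 0
    eps <- 1e-9 * max(abs(flux$Y_sum), abs(flux$Mp), abs(flux$Rp), turnover)
  }
  if (eps < 0) stop_domain("`eps` must be >= 0")
  sY <- sign_deadband(flux$Y_sum, eps)
  sM <- sign_deadband(flux$Mp, eps)
  sR <- sign_deadband(flux$Rp, eps)
  lab <- character(length(sY))
  for (k in seq_along(sY)) {
    lab[k] <-
      if (sY[k] > 0) {
        if (sM[k] > 0 && sR[k] >= 0) "a"
        else if (sM[k] > 0 && sR[k] < 0) "b"
        else if (sM[k] <= 0 && sR[k] < 0) "c"
        else "mixed"
      } else if (sY[k] < 0) {
        if (sM[k] >= 0 && sR[k] > 0) "d"
        else if (sM[k] < 0 && sR[k] > 0) "e"
        else if (sM[k] < 0 && sR[k] < 0) "f"
        else "mixed"
      } else {
        if (sM[k] > 0 && sR[k] > 0) "g"
        else if (sM[k] < 0 && sR[k] < 0) "h"
        else if (sM[k] == 0 && sR[k] == 0) "null"
        else "mixed"
      }
  }
  lab
}

#' Memory-equilibrium dichotomy diagnostic
#'
#' Under an absolutely continuous (density) memory measure, the flux
#' functional vanishes identically only for the trivial (extinct)
#' trajectory.  This diagnostic reports `sup|Y|` and `sup|N|` over the
#' window and checks the dichotomy numerically: a nontrivial trajectory
#' must have `sup|Y|` above `floor`, and a numerically extinct one must
#' have `sup|Y| <= tol`.
#'
#' @param flux a `flux_series` computed with a density measure.
#' @param floor pinned positive lower bound on `sup|Y|` for nontrivial
#'   trajectories (fixture-specific, from a reference run).
#' @param tol threshold below which the trajectory/flux count as zero.
#' @return list with `sup_Y`, `sup_N`, `nontrivial`, `consistent`.
#' @export
memory_equilibrium_diagnostic <- function(flux, floor = 0, tol = 1e-9) {
  stopifnot(inherits(flux, "flux_series"))
  if (flux$measure_kind != "density")
    stop_domain("the dichotomy applies to density (memory) measures only; got '%s'",
                flux$measure_kind)
  sup_Y <- max(abs(flux$Y_sum))
  sup_N <- flux$max_abs_N
  nontrivial <- sup_N > tol
  consistent <- if (nontrivial) sup_Y > floor else sup_Y <= tol
  list(sup_Y = sup_Y, sup_N = sup_N, nontrivial = nontrivial,
       consistent = consistent)
}

#' Write a flux series to CSV
#'
#' Header `t,tau_1..tau_n,R,M,dM,dR,Y_sum,Y_budget,scenario`.
#'
#' @param flux a `flux_series`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_flux_csv <- function(flux, path) {
  n <- ncol(flux$tau)
  header <- c("t", paste0("tau_", seq_len(n)), "R", "M", "dM", "dR",
              "Y_sum", "Y_budget", "scenario")
  num <- cbind(flux$t, flux$tau, flux$R, flux$M, flux$Mp, flux$Rp,
               flux$Y_sum, flux$Y_budget)
  lines <- vapply(seq_len(nrow(num)), function(k)
    paste(c(sprintf("%.17g", num[k, ]), flux$scenario[k]), collapse = ","),
    character(1L))
  writeLines(c(paste(header, collapse = ","), lines), path)
  invisible(path)
}
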