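# Trophic functionals tau_i under memory measures, their time
# derivatives, the weight-bound check, and the Picard iteration for the
# associated Volterra integral equation.

# f_i(s) = p_i(s, N(s), cum(s)) * N_i(s) on selected grid rows.
f_values <- function(trajectory, weights, rows) {
  n <- trajectory$model$n
  out <- matrix(NA_real_, length(rows), n)
  for (j in seq_along(rows)) {
    k <- rows[j]
    p <- weights$p(trajectory$t[k], trajectory$N[k, ], trajectory$cumN[k, ])
    out[j, ] <- p * trajectory$N[k, ]
  }
  out
}

# Composite-trapezoid node weights for abscissae s.
trapz_weights <- function(s) {
  k <- length(s)
  if (k == 1L) return(0)
  ds <- diff(s)
  c(ds[1L] / 2, if (k > 2L) (ds[-1L] + ds[-(k - 1L)]) / 2, ds[k - 1L] / 2)
}

#' Trophic functional under a memory measure
#'
#' Evaluates, for every species, the history-weighted trophic functional
#' \deqn{\tau_i(t) = \frac{1}{t} \int_0^t p_i(s) N_i(s)\, d\mu_t(s),}
#' where \eqn{p_i} is the effective trophic potential.  For a density
#' measure the integral uses the composite trapezoid rule on the
#' trajectory's own output grid restricted to `[0, t]` (with an
#' interpolated endpoint node when `t` falls between grid points); for
#' the Dirac measure \eqn{\mu_t = t\,\delta(t-s)} the prefactor cancels
#' and \eqn{\tau_i(t) = p_i(t) N_i(t)} exactly.  At `t = 0` the density
#' case is defined by its limit, \eqn{p_i(0) N_i(0) w(0, 0)}.
#'
#' @param trajectory a `glv_trajectory`.
#' @param weights a [trophic_weights()] object.
#' @param measure a [gaussian_measure()], [density_measure()] or
#'   [dirac_measure()].
#' @param t evaluation time within the trajectory span.
#' @return numeric vector of length `n` (mass units).
#' @export
trophic_functional <- function(trajectory, weights, measure, t) {
  stopifnot(inherits(trajectory, "glv_trajectory"),
            inherits(weights, "trophic_weights"),
            inherits(measure, "memory_measure"))
  tt <- trajectory$t
  if (t < tt[1L] - 1e-12 || t > tt[length(tt)] + 1e-12 * (1 + abs(t)))
    stop_domain("t = %g outside trajectory span", t)
  st <- state_at(trajectory, t)
  pt <- weights$p(t, st$N, st$cumN)
  if (measure$kind == "dirac") return(unname(pt * st$N))
  if (t <= 0) return(unname(pt * st$N * measure$w(0, 0)))
  idx <- which(tt <= t + 1e-12 * (1 + abs(t)))
  s <- tt[idx]
  f <- f_values(trajectory, weights, idx)
  if (t > s[length(s)] + 1e-10 * (1 + abs(t))) {
    s <- c(s, t)
    f <- rbind(f, pt * st$N)
  }
  q <- trapz_weights(s) * measure$w(t, s)
  unname(as.vector(crossprod(f, q)) / t)
}

#' Time derivative of the trophic functional
#'
#' For a density measure with density `w` the derivative is the
#' three-term expression
#' \deqn{\frac{d\tau_i}{dt} = -\frac{1}{t^2}\int_0^t f_i w_t\,ds
#'   + \frac{1}{t}\Big[f_i(t) w_t(t)
#'   + \int_0^t f_i \frac{\partial w_t}{\partial t}\,ds\Big],}
#' with \eqn{f_i = p_i N_i}, evaluated with the same quadrature rule as
#' [trophic_functional()].  For the Dirac measure it is the total
#' derivative of \eqn{p_i N_i} by the chain rule, using the GLV
#' right-hand side for \eqn{dN_i/dt} and the weights' analytic `dp_dt`
#' when available (finite differences along the trajectory otherwise).
#'
#' @inheritParams trophic_functional
#' @return numeric vector of length `n` (mass per time).
#' @export
trophic_derivative <- function(trajectory, weights, measure, t) {
  stopifnot(inherits(measure, "memory_measure"))
  tt <- trajectory$t
  if (t < tt[1L] - 1e-12 || t > tt[length(tt)] + 1e-12 * (1 + abs(t)))
    stop_domain("t = %g outside trajectory span", t)
  st <- state_at(trajectory, t)
  if (measure$kind == "dirac") {
    Ndot <- glv_rhs(trajectory$model, st$N)
    p <- weights$p(t, st$N, st$cumN)
    dp <- weights_dp(trajectory, weights, t, st)
    return(unname(dp * st$N + p * Ndot))
  }
  if (t <= 0) stop_domain("density-measure derivative needs t > 0")
  pt <- weights$p(t, st$N, st$cumN)
  ft <- pt * st$N
  idx <- which(tt <= t + 1e-12 * (1 + abs(t)))
  s <- tt[idx]
  f <- f_values(trajectory, weights, idx)
  if (t > s[length(s)] + 1e-10 * (1 + abs(t))) {
    s <- c(s, t)
    f <- rbind(f, ft)
  }
  wq <- trapz_weights(s)
  I1 <- as.vector(crossprod(f, wq * measure$w(t, s)))
  I2 <- as.vector(crossprod(f, wq * measure$dw_dt(t, s)))
  unname(-I1 / t^2 + (ft * measure$w(t, t) + I2) / t)
}

# Total derivative of p along the trajectory: analytic when supplied,
# otherwise central differences of p evaluated on interpolated states.
weights_dp <- function(trajectory, weights, t, st) {
  if (!is.null(weights$dp_dt)) return(weights$dp_dt(t, st$N, st$cumN))
  span <- range(trajectory$t)
  h <- min(1e-5 * (1 + abs(t)), (span[2L] - span[1L]) / 10)
  tm <- max(t - h, span[1L]); tp <- min(t + h, span[2L])
  sm <- state_at(trajectory, tm); sp <- state_at(trajectory, tp)
  (weights$p(tp, sp$N, sp$cumN) - weights$p(tm, sm$N, sm$cumN)) / (tp - tm)
}

#' Trophic series on the whole trajectory grid
#'
#' Evaluates `tau` and `dtau_dt` at every output time.  For density
#' measures this shares one pass of kernel evaluations per grid point
#' (cost quadratic in grid length); the first-point derivative, where
#' the `1/t` prefactor is singular, is filled by a forward difference.
#'
#' @inheritParams trophic_functional
#' @return an object of class `trophic_series`: list with `t`, matrices
#'   `tau` and `dtau_dt` (times x species), `measure_kind`, and the
#'   potential matrix `p`.
#' @export
trophic_series <- function(trajectory, weights, measure) {
  stopifnot(inherits(trajectory, "glv_trajectory"),
            inherits(weights, "trophic_weights"),
            inherits(measure, "memory_measure"))
  tt <- trajectory$t
  m <- length(tt)
  n <- trajectory$model$n
  f <- f_values(trajectory, weights, seq_len(m))
  pmat <- f / trajectory$N
  tau <- matrix(NA_real_, m, n)
  dtau <- matrix(NA_real_, m, n)
  if (measure$kind == "dirac") {
    tau <- f
    for (k in seq_len(m)) {
      st <- list(N = trajectory$N[k, ], cumN = trajectory$cumN[k, ])
      Ndot <- glv_rhs(trajectory$model, st$N)
      dp <- weights_dp(trajectory, weights, tt[k], st)
      dtau[k, ] <- dp * st$N + pmat[k, ] * Ndot
    }
  } else {
    tau[1L, ] <- f[1L, ] * measure$w(0, 0)
    for (k in 2:m) {
      s <- tt[seq_len(k)]
      wq <- trapz_weights(s)
      wv <- measure$w(tt[k], s)
      dwv <- measure$dw_dt(tt[k], s)
      fi <- f[seq_len(k), , drop = FALSE]
      I1 <- as.vector(crossprod(fi, wq * wv))
      I2 <- as.vector(crossprod(fi, wq * dwv))
      tau[k, ] <- I1 / tt[k]
      dtau[k, ] <- -I1 / tt[k]^2 + (f[k, ] * measure$w(tt[k], tt[k]) + I2) / tt[k]
    }
    dtau[1L, ] <- (tau[2L, ] - tau[1L, ]) / (tt[2L] - tt[1L])
  }
  colnames(tau) <- colnames(dtau) <- trajectory$model$labels
  structure(list(t = tt, tau = tau, dtau_dt = dtau, p = pmat,
                 measure_kind = measure$kind),
            class = "trophic_series")
}

#' Check the physiological weight bound
#'
#' Verifies the standing constraint \eqn{p_i \le C_i} over the whole
#' trajectory and reports the first violating time per species, if any.
#'
#' @inheritParams trophic_functional
#' @return an object of class `weight_bound_report`: `ok` (logical),
#'   and a data frame `per_species` with columns `species`, `max_p`,
#'   `C`, `ok`, `first_violation_time`.
#' @export
check_weight_bound <- function(trajectory, weights) {
  if (is.null(weights$C))
    stop_domain("weights carry no bound `C`; nothing to check")
  m <- length(trajectory$t)
  pmat <- f_values(trajectory, weights, seq_len(m)) / trajectory$N
  n <- ncol(pmat)
  C <- rep_len(weights$C, n)
  viol_time <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    bad <- which(pmat[, i] > C[i])
    if (length(bad)) viol_time[i] <- trajectory$t[bad[1L]]
  }
  per <- data.frame(species = trajectory$model$labels,
                    max_p = apply(pmat, 2L, max), C = C,
                    ok = is.na(viol_time),
                    first_violation_time = viol_time)
  structure(list(ok = all(per$ok), per_species = per),
            class = "weight_bound_report")
}

#' Volterra kernel of a density memory measure
#'
#' The homogeneous Volterra equation underlying the memory-equilibrium
#' dichotomy has kernel
#' \eqn{K(t, s) = (w_t(s)/t - \partial w_t/\partial t(s)) / w_t(t)}.
#'
#' @param measure a density-kind `memory_measure`.
#' @return a function `(t, s) -> kernel values` (vectorized over `s`).
#' @export
measure_kernel <- function(measure) {
  if (measure$kind != "density")
    stop_domain("the Volterra kernel is defined for density measures only")
  function(t, s) (measure$w(t, s) / t - measure$dw_dt(t, s)) / measure$w(t, t)
}

#' Picard iteration for the Volterra integral equation
#'
#' Iterates \eqn{\varphi_{k+1}(t) = \int_0^t \varphi_k(s) K(t, s)\, ds}
#' from \eqn{\varphi_0 \equiv 1} on a uniform grid over `[0, T]` and
#' returns the sequence of sup-norms \eqn{\|\varphi_k\|_\infty}.  Decay
#' toward zero numerically confirms that the homogeneous equation admits
#' only the trivial solution.  Note that kernels derived from memory
#' densities carry a `1/t` singularity at the origin, where the Picard
#' operator acts like a running average; decay there is slow (but still
#' present), so many iterations may be needed before the sup-norm drops
#' below a small threshold.
#'
#' @param kernel function `(t, s) -> real`, vectorized over `s`.
#' @param T horizon, `> 0`.
#' @param iterations number of Picard steps, `>= 1`.
#' @param grid_n number of grid points (default 2048).
#' @return numeric vector of length `iterations` of sup-norms.
#' @examples
#' volterra_trivial_check(function(t, s) rep(1, length(s)), 1, 5)  # 1/k!
#' @export
volterra_trivial_check <- function(kernel, T, iterations, grid_n = 2048) {
  stopifnot(is.function(kernel), T > 0, iterations >= 1)
  tgrid <- seq(0, T, length.out = grid_n)
  h <- tgrid[2L] - tgrid[1L]
  M <- matrix(0, grid_n, grid_n)
  for (i in 2:grid_n) {
    w <- rep(h, i)
    w[1L] <- h / 2
    w[i] <- h / 2
    M[i, seq_len(i)] <- w * kernel(tgrid[i], tgrid[seq_len(i)])
  }
  phi <- rep(1, grid_n)
  sup <- numeric(iterations)
  for (k in seq_len(iterations)) {
    phi <- as.vector(M %*% phi)
    sup[k] <- max(abs(phi))
  }
  sup
}
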