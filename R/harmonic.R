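# The exponential (harmonic) trophic potential, its Laplacian residual,
# the algebraic harmonicity constraint, and the n = 2 conic analysis.

#' Harmonic (exponential) trophic weights
#'
#' The distinguished choice of effective trophic potential
#' \deqn{p_i(t) = \exp\Big(-r_i t - \sum_j a_{ij} \int_0^t N_j(s)\,ds\Big)}
#' makes every Dirac-measure trophic functional a conserved quantity:
#' \eqn{\tau_i(t) = p_i(t) N_i(t) = N_i(0)} along any GLV trajectory,
#' so the flux functional `Y` vanishes identically.  The analytic total
#' derivative \eqn{dp_i/dt = -(r_i + (AN)_i)\, p_i} is attached.
#'
#' @param model a [glv_model()].
#' @return a [trophic_weights()] object (label `"harmonic"`).
#' @examples
#' w <- harmonic_weights(wolf_rabbit_model())
#' w$p(0, c(1500, 60), c(0, 0))  # c(1, 1): empty exponent
#' @export
harmonic_weights <- function(model) {
  stopifnot(inherits(model, "glv_model"))
  trophic_weights(
    p = function(t, N, cumN)
      exp(-model$r * t - as.vector(model$A %*% cumN)),
    dp_dt = function(t, N, cumN)
      -as.vector(model$r + model$A %*% N) *
        exp(-model$r * t - as.vector(model$A %*% cumN)),
    label = "harmonic")
}

#' Laplacian residual of the harmonic trophic potential
#'
#' Treating `(t, N_1, ..., N_n)` as independent coordinates, the
#' Laplacian of the exponential potential reduces to its second time
#' derivative,
#' \deqn{\Delta p_i = \Big[(r_i + \sum_j a_{ij} N_j(t))^2
#'   - \sum_j a_{ij} \dot N_j(t)\Big] p_i,}
#' with \eqn{\dot N_j} from the GLV right-hand side.  A zero residual
#' means `p_i` is (numerically) harmonic at that point of the
#' trajectory.
#'
#' @param model a [glv_model()].
#' @param trajectory a `glv_trajectory` of the same model.
#' @param t a time on the trajectory grid.
#' @return numeric vector of per-species residuals \eqn{\Delta p_i}.
#' @export
laplacian_residual <- function(model, trajectory, t) {
  stopifnot(inherits(model, "glv_model"), inherits(trajectory, "glv_trajectory"))
  k <- which(abs(trajectory$t - t) <= 1e-9 * (1 + abs(t)))
  if (!length(k)) stop_domain("t = %g is not on the trajectory grid", t)
  k <- k[1L]
  N <- trajectory$N[k, ]
  cumN <- trajectory$cumN[k, ]
  p <- exp(-model$r * t - as.vector(model$A %*% cumN))
  g <- as.vector(model$r + model$A %*% N)
  Ndot <- glv_rhs(model, N)
  (g^2 - as.vector(model$A %*% Ndot)) * p
}

#' Algebraic harmonicity constraint of a GLV model
#'
#' Requiring every exponential trophic potential to be harmonic forces
#' the quadratic identity
#' \deqn{\sum_i \Big[r_i^2 + \sum_j a_{ij}(2 r_i - r_j) N_j
#'   + \sum_{j,k} a_{ij}(a_{ik} - a_{jk}) N_j N_k\Big] = 0}
#' on the population state.  `constraint_coefficients()` collects it as
#' a constant \eqn{\gamma_0 = \sum_i r_i^2 \ge 0}, a linear form `L`,
#' and a quadratic form `Q` (stored symmetrized; the raw asymmetric
#' version is kept for cross-checks).  `constraint_evaluate()` returns
#' \eqn{\gamma_0 + L N + N^T Q N}; it vanishes identically at any
#' interior equilibrium.
#'
#' @param model a [glv_model()].
#' @return an object of class `harmonicity_constraint` with fields `n`,
#'   `constant`, `linear`, `Q` (symmetrized), `Q_raw`.
#' @examples
#' hc <- constraint_coefficients(wolf_rabbit_model())
#' constraint_evaluate(hc, c(1000, 80))  # 0 at the equilibrium
#' @export
constraint_coefficients <- function(model) {
  stopifnot(inherits(model, "glv_model"))
  r <- model$r
  A <- model$A
  n <- model$n
  gamma0 <- sum(r^2)
  # L_j = sum_i a_ij (2 r_i - r_j)
  L <- as.vector(crossprod(A, 2 * r)) - colSums(A) * r
  # raw Q_jk = sum_i a_ij (a_ik - a_jk)
  Q_raw <- crossprod(A, A) - colSums(A) * A
  Q <- (Q_raw + t(Q_raw)) / 2
  structure(list(n = n, constant = gamma0, linear = L, Q = Q, Q_raw = Q_raw),
            class = "harmonicity_constraint")
}

#' @rdname constraint_coefficients
#' @param constraint a `harmonicity_constraint`.
#' @param N abundance vector of length `n`.
#' @export
constraint_evaluate <- function(constraint, N) {
  stopifnot(inherits(constraint, "harmonicity_constraint"))
  N <- as.numeric(N)
  if (length(N) != constraint$n) stop_domain("`N` must have length n")
  constraint$constant + sum(constraint$linear * N) +
    as.numeric(t(N) %*% constraint$Q %*% N)
}

#' @export
print.harmonicity_constraint <- function(x, ...) {
  cat(sprintf("<harmonicity_constraint> n=%d, gamma0=%.6g\n", x$n, x$constant))
  invisible(x)
}

#' Conic form of the two-species harmonicity constraint
#'
#' For `n = 2` the harmonicity constraint is a conic in the
#' `(N1, N2)` phase plane.  The six normalized coefficients are
#' \deqn{c_1 = a_{21}(a_{21}-a_{11})/K,\;
#'   c_2 = [a_{12}(a_{11}-a_{21}) + a_{21}(a_{22}-a_{12})]/K,\;
#'   c_3 = a_{12}(a_{12}-a_{22})/K,}
#' \deqn{c_4 = [a_{12}(2r_1-r_2) + a_{22} r_2]/K,\;
#'   c_5 = [a_{11} r_1 + a_{21}(2r_2-r_1)]/K,\;
#'   c_6 = -(r_1^2+r_2^2)/K,}
#' with normalization `K = r1^2 + r2^2` when positive (so `c6 = -1`)
#' and `K = 1` otherwise.  The classification uses the discriminant
#' `D = cross^2 - 4 q11 q22` of the *unnormalized* quadratic part, so
#' it is invariant under any positive rescaling of `K`.  For this
#' constraint `D` is algebraically the perfect square
#' `[a12(a11-a21) - a21(a22-a12)]^2`, hence never negative: the
#' harmonicity conic is hyperbolic or degenerate/parabolic, never
#' elliptic (closed elliptic orbits in phase portraits arise from the
#' GLV dynamics themselves, not from this curve).
#'
#' @param model a two-species [glv_model()].
#' @param K optional positive normalization overriding the default.
#' @return an object of class `conic_coefficients`: `c` (c1..c6), `K`,
#'   `q` (unnormalized quadratic coefficients `q11`, `cross`, `q22`),
#'   `D`, `conic_class` in
#'   `{"degenerate/parabolic", "hyperbolic", "elliptic"}`.
#' @export
conic_coefficients_2d <- function(model, K = NULL) {
  stopifnot(inherits(model, "glv_model"))
  if (model$n != 2L) stop_domain("conic analysis requires n = 2")
  r <- model$r
  A <- model$A
  a11 <- A[1, 1]; a12 <- A[1, 2]; a21 <- A[2, 1]; a22 <- A[2, 2]
  q11 <- a21 * (a21 - a11)
  q22 <- a12 * (a12 - a22)
  cross <- a12 * (a11 - a21) + a21 * (a22 - a12)
  if (is.null(K)) K <- if (sum(r^2) > 0) sum(r^2) else 1
  if (K <= 0) stop_domain("`K` must be positive")
  cc <- c(c1 = q11 / K,
          c2 = cross / K,
          c3 = q22 / K,
          c4 = (a12 * (2 * r[1] - r[2]) + a22 * r[2]) / K,
          c5 = (a11 * r[1] + a21 * (2 * r[2] - r[1])) / K,
          c6 = -sum(r^2) / K)
  D <- cross^2 - 4 * q11 * q22
  tol <- 1e-12 * (1 + max(abs(c(q11, q22, cross)))^2)
  klass <- if (D > tol) "hyperbolic"
           else if (D < -tol) "elliptic"
           else "degenerate/parabolic"
  structure(list(c = cc, K = K, q = c(q11 = q11, cross = cross, q22 = q22),
                 D = D, conic_class = klass, tol = tol),
            class = "conic_coefficients")
}

#' @export
print.conic_coefficients <- function(x, ...) {
  cat(sprintf("<conic_coefficients> %s (D = %.6g, K = %.6g)\n",
              x$conic_class, x$D, x$K))
  print(x$c)
  invisible(x)
}

#' Sample the harmonicity constraint over a phase-space window
#'
#' Evaluates the constraint on a dense `n1 x n2` grid; the sign pattern
#' locates the zero set (the harmonicity curve) without any marching
#' step.
#'
#' @param constraint a `harmonicity_constraint` with `n = 2`.
#' @param N1_range,N2_range numeric length-2 windows.
#' @param resolution grid points per axis.
#' @return data frame with columns `N1`, `N2`, `value`.
#' @export
constraint_grid_2d <- function(constraint, N1_range, N2_range,
                               resolution = 200L) {
  if (constraint$n != 2L) stop_domain("grid sampling requires n = 2")
  g1 <- seq(N1_range[1L], N1_range[2L], length.out = resolution)
  g2 <- seq(N2_range[1L], N2_range[2L], length.out = resolution)
  grid <- expand.grid(N1 = g1, N2 = g2)
  v <- constraint$constant +
    constraint$linear[1L] * grid$N1 + constraint$linear[2L] * grid$N2 +
    constraint$Q[1L, 1L] * grid$N1^2 + constraint$Q[2L, 2L] * grid$N2^2 +
    2 * constraint$Q[1L, 2L] * grid$N1 * grid$N2
  grid$value <- v
  grid
}
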