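#' Interior coexistence equilibrium of a GLV model
#'
#' Solves `r + A N* = 0`.  The solution is returned only when it is
#' finite and strictly positive (an interior fixed point); a singular
#' interaction matrix or a non-positive solution yields `NULL` --
#' absence is a value, not an error.
#'
#' @param model a [glv_model()].
#' @return a named abundance vector, or `NULL`.
#' @examples
#' coexistence_equilibrium(wolf_rabbit_model())  # c(rabbit = 1000, wolf = 80)
#' @export
coexistence_equilibrium <- function(model) {
  stopifnot(inherits(model, "glv_model"))
  Nstar <- tryCatch(solve(model$A, -model$r), error = function(e) NULL)
  if (is.null(Nstar)) return(NULL)
  Nstar <- as.vector(Nstar)
  if (any(!is.finite(Nstar)) || any(Nstar <= 0)) return(NULL)
  stats::setNames(Nstar, model$labels)
}

#' Local stability analysis at a positive state
#'
#' The community (Jacobian) matrix of the GLV vector field at a state
#' `N` is `J = diag(N) A + diag(r + A N)`; at an interior equilibrium the
#' second term vanishes and `J = diag(N*) A`.  Eigenvalues are
#' classified by the signs of their real parts, with real parts below
#' `tol = 1e-9` times the spectral radius treated as zero, so a purely
#' imaginary pair is reported as a (linear) center.
#'
#' @param model a [glv_model()].
#' @param point strictly positive state vector.
#' @return an object of class `equilibrium_report` with fields `point`,
#'   `jacobian`, `eigenvalues`, `classification` (one of
#'   `"stable node"`, `"unstable node"`, `"saddle"`, `"center (linear)"`,
#'   `"stable focus"`, `"unstable focus"`, `"degenerate"`), and the
#'   fixed-point residual `r + A point`.
#' @examples
#' stability_at(wolf_rabbit_model(), c(1000, 80))  # center, eigenvalues +-0.2i
#' @export
stability_at <- function(model, point) {
  stopifnot(inherits(model, "glv_model"))
  point <- as.numeric(point)
  if (length(point) != model$n) stop_domain("`point` must have length n")
  if (any(!is.finite(point)) || any(point <= 0))
    stop_domain("`point` must be strictly positive")
  n <- model$n
  residual <- as.vector(model$r + model$A %*% point)
  J <- diag(point, nrow = n) %*% model$A + diag(residual, nrow = n)
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(point = point, jacobian = J, eigenvalues = ev,
                 residual = residual,
                 classification = classify_eigenvalues(ev)),
            class = "equilibrium_report")
}

# Pure function of the spectrum; |Re| < 1e-9 * spectral radius counts as zero.
classify_eigenvalues <- function(ev, tol_factor = 1e-9) {
  rho <- max(abs(ev))
  if (rho == 0) return("degenerate")
  tol <- tol_factor * rho
  re <- Re(ev); im <- Im(ev)
  zero_re <- abs(re) <= tol
  oscillatory <- any(abs(im) > tol)
  if (all(zero_re)) return(if (oscillatory) "center (linear)" else "degenerate")
  if (any(zero_re)) return("degenerate")
  if (all(re < 0)) return(if (oscillatory) "stable focus" else "stable node")
  if (all(re > 0)) return(if (oscillatory) "unstable focus" else "unstable node")
  "saddle"
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("<equilibrium_report> %s\n", x$classification))
  cat("point:      ", format(x$point, digits = 6), "\n")
  cat("eigenvalues:", format(x$eigenvalues, digits = 6), "\n")
  invisible(x)
}
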