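#' Trophic weights: the effective trophic potential per individual
#'
#' The per-individual weight of species `i` in the biomass budget is the
#' product \eqn{p_i = \bar m_i k_i} of mean individual biomass and
#' relative trophic strength.  Every formula in the framework uses the
#' two factors only through their product, so the package houses `p`
#' alone; `p` is a function of time, the state vector, and the vector of
#' running abundance integrals, and must return strictly positive finite
#' values.  An optional per-species cap `C` encodes the physiological
#' bound \eqn{p_i \le C_i}, checked by [check_weight_bound()].
#'
#' @param p function `(t, N, cumN) -> positive vector of length n`.
#' @param dp_dt optional analytic total time derivative along the
#'   trajectory, same signature; when absent, derivative-based
#'   operations fall back to finite differences along the trajectory.
#' @param C optional positive cap vector.
#' @param label short provenance tag.
#' @return an object of class `trophic_weights`.
#' @seealso [constant_weights()], [harmonic_weights()]
#' @export
trophic_weights <- function(p, dp_dt = NULL, C = NULL, label = "custom") {
  stopifnot(is.function(p))
  if (!is.null(C) && any(C <= 0)) stop_domain("bound `C` must be positive")
  structure(list(p = p, dp_dt = dp_dt, C = C, label = label),
            class = "trophic_weights")
}

#' Constant trophic weights
#'
#' @param p positive numeric vector (recycled to species count at use).
#' @inheritParams trophic_weights
#' @return a `trophic_weights` object with `p` constant in time and state.
#' @export
constant_weights <- function(p, C = NULL) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p <= 0)) stop_domain("`p` must be positive")
  trophic_weights(
    p = function(t, N, cumN) rep_len(p, length(N)),
    dp_dt = function(t, N, cumN) rep_len(0, length(N)),
    C = C, label = "constant")
}

#' @export
print.trophic_weights <- function(x, ...) {
  cat(sprintf("<trophic_weights> %s%s\n", x$label,
              if (is.null(x$C)) "" else " (bounded)"))
  invisible(x)
}

# Build weights from a declarative spec; needs the model for the
# harmonic kind.
build_weights <- function(spec, model = NULL) {
  switch(spec$kind %||% stop_domain("weights spec needs a `kind`"),
         harmonic = harmonic_weights(model),
         constant = constant_weights(spec$p %||% 1, C = spec$C),
         stop_domain("unknown weights kind '%s'", spec$kind))
}
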