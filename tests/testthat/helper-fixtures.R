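# Shared helpers: tiny analytic models and independent oracles.

# One-species exponential / logistic models (closed forms known).
exp_model <- function(r = 1) glv_model(r = r, A = matrix(0, 1, 1))
logistic_model <- function(r = 1, k = 1) glv_model(r = r, A = matrix(-r / k, 1, 1))

logistic_solution <- function(t, N0, r = 1, k = 1) {
  k / (1 + (k / N0 - 1) * exp(-r * t))
}

# Draw a random GLV model (entries of modest size, any signs).
random_model <- function(n) {
  glv_model(r = stats::runif(n, -1, 1),
            A = matrix(stats::runif(n * n, -1, 1), n, n))
}

# Independent brute-force oracle for the harmonicity identity: literal
# triple-sum substitution, no shared code with constraint_evaluate().
brute_constraint <- function(model, N) {
  r <- model$r; A <- model$A; n <- model$n
  total <- 0
  for (i in seq_len(n)) {
    acc <- r[i]^2
    for (j in seq_len(n)) {
      acc <- acc + A[i, j] * (2 * r[i] - r[j]) * N[j]
      for (k in seq_len(n)) {
        acc <- acc + A[i, j] * (A[i, k] - A[j, k]) * N[j] * N[k]
      }
    }
    total <- total + acc
  }
  total
}

# Synthetic circular orbit injected as a trajectory object, bypassing
# the ODE solver: N(t) = (c1 + rho cos t, c2 + rho sin t).
circular_trajectory <- function(c1 = 5, c2 = 3, rho = 1,
                                t_end = 4 * pi, dt = 0.005) {
  t <- seq(0, t_end, by = dt)
  N <- cbind(c1 + rho * cos(t), c2 + rho * sin(t))
  model <- glv_model(r = c(0, 0), A = matrix(0, 2, 2))
  colnames(N) <- model$labels
  cumN <- apply(N, 2L, function(y) glvflux:::cum_trapz(t, y))
  structure(list(model = model, t = t, N = N, cumN = cumN,
                 N0 = N[1L, ], dt_out = dt, rtol = NA, atol = NA,
                 method = "synthetic"),
            class = "glv_trajectory")
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
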