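# Harmonic trophic potential, algebraic constraint, conic analysis.

test_that("harmonic weights conserve the Dirac trophic functional", {
  # empty exponent at t = 0
  wr <- wolf_rabbit_model()
  hw <- harmonic_weights(wr)
  expect_equal(hw$p(0, c(1500, 60), c(0, 0)), c(1, 1))

  # one species, no interaction: p = e^{-t}, N = N0 e^t, tau = N0
  me <- exp_model(1)
  tre <- integrate_glv(me, 2.5, t_end = 3, dt_out = 0.01)
  ts <- trophic_series(tre, harmonic_weights(me), dirac_measure())
  expect_lt(max(abs(ts$tau - 2.5)) / 2.5, 1e-9)

  # the full predator-prey orbit: tau_i(t) = N_i(0) over three periods
  tr <- integrate_glv(wr, c(1500, 60), t_end = 110, dt_out = 0.05)
  ts <- trophic_series(tr, harmonic_weights(wr), dirac_measure())
  expect_lt(max(abs(t(ts$tau) - c(1500, 60)) / c(1500, 60)), 1e-6)
  # consequently the flux functional vanishes relative to gross turnover
  gross <- max(abs(ts$p * t(apply(tr$N, 1, function(N) glv_rhs(wr, N)))))
  expect_lt(max(abs(rowSums(ts$dtau_dt))), 1e-6 * gross)
})

test_that("Laplacian residual matches hand-computed potentials", {
  m0 <- glv_model(0, matrix(0, 1, 1))      # p = 1, constant
  tr0 <- integrate_glv(m0, 1, t_end = 1, dt_out = 0.1)
  expect_equal(laplacian_residual(m0, tr0, 0.5), 0)

  me <- exp_model(1)                       # p = e^{-t}: residual p'' = e^{-t}
  tre <- integrate_glv(me, 1, t_end = 1, dt_out = 0.1)
  expect_equal(laplacian_residual(me, tre, 0), 1)
  expect_equal(laplacian_residual(me, tre, 0.5), exp(-0.5), tolerance = 1e-9)

  expect_error(laplacian_residual(me, tre, 0.123), "grid")
})

test_that("summed scaled residuals equal the algebraic constraint", {
  wr <- wolf_rabbit_model()
  tr <- integrate_glv(wr, c(1200, 100), t_end = 10, dt_out = 0.1)
  hc <- constraint_coefficients(wr)
  for (t in c(0, 2.5, 7.5)) {
    k <- which.min(abs(tr$t - t))
    N <- tr$N[k, ]
    cumN <- tr$cumN[k, ]
    p <- exp(-wr$r * t - as.vector(wr$A %*% cumN))
    res <- laplacian_residual(wr, tr, tr$t[k])
    expect_equal(sum(res / p), constraint_evaluate(hc, N), tolerance = 1e-10)
  }
})

test_that("constraint coefficients match direct expansion for the preset", {
  hc <- constraint_coefficients(wolf_rabbit_model())
  expect_equal(hc$constant, 0.08^2 + 0.5^2)
  expect_equal(hc$linear, c(5e-4 * (-1.08), -1e-3 * 0.66), tolerance = 1e-15)
  expect_equal(hc$Q[1, 1], 2.5e-7)
  expect_equal(hc$Q[2, 2], 1e-6)
  expect_equal(2 * hc$Q[1, 2], 1e-6)      # symmetrized cross term
  expect_equal(constraint_evaluate(hc, c(1000, 80)), 0, tolerance = 1e-12)

  zero <- constraint_coefficients(glv_model(c(0, 0), matrix(0, 2, 2)))
  expect_equal(zero$constant, 0)
  expect_equal(zero$linear, c(0, 0))
  expect_equal(zero$Q, matrix(0, 2, 2))
  expect_equal(constraint_evaluate(zero, c(3, 4)), 0)
})

test_that("constraint evaluation equals the brute-force triple sum", {
  set.seed(42)
  for (case in 1:100) {
    n <- sample(2:4, 1)
    m <- random_model(n)
    N <- stats::runif(n, 0, 5)
    hc <- constraint_coefficients(m)
    fast <- constraint_evaluate(hc, N)
    brute <- brute_constraint(m, N)
    scale <- 1 + abs(hc$constant) + sum(abs(hc$linear * N)) +
      sum(abs(hc$Q %*% N * N))
    expect_lt(abs(fast - brute), 1e-12 * scale)
  }
})

test_that("the constraint vanishes at any interior equilibrium", {
  set.seed(7)
  for (case in 1:50) {
    n <- sample(2:4, 1)
    A <- matrix(stats::runif(n * n, -1, 1), n, n)
    if (abs(det(A)) < 1e-3) next
    x <- stats::runif(n, 0.2, 3)
    m <- glv_model(-as.vector(A %*% x), A)
    hc <- constraint_coefficients(m)
    scale <- 1 + abs(hc$constant) + sum(abs(hc$linear * x)) +
      sum(abs(hc$Q %*% x * x))
    expect_lt(abs(constraint_evaluate(hc, x)), 1e-10 * scale)
  }
})

test_that("conic coefficients and classification follow the printed formulas", {
  # worked quadratic example: coefficients (2, 5, 2), hyperbolic
  m <- glv_model(c(0.3, -0.2), matrix(c(-1, 1, -2, -1), 2, 2))
  cc <- conic_coefficients_2d(m)
  expect_equal(unname(cc$q), c(2, 5, 2))
  expect_equal(cc$D, 9)
  expect_identical(cc$conic_class, "hyperbolic")
  expect_equal(unname(cc$c["c6"]), -1)     # K = r1^2 + r2^2 normalization

  # degenerate normalization branch
  m0 <- glv_model(c(0, 0), matrix(c(-1, 1, -2, -1), 2, 2))
  cc0 <- conic_coefficients_2d(m0)
  expect_equal(cc0$K, 1)
  expect_equal(unname(cc0$c["c6"]), 0)

  expect_error(conic_coefficients_2d(exp_model()), "n = 2")
})

test_that("zero-diagonal pairs are always degenerate/parabolic (D = 0)", {
  set.seed(3)
  for (case in 1:50) {
    A <- matrix(c(0, stats::runif(1, -2, 2), stats::runif(1, -2, 2), 0), 2, 2)
    m <- glv_model(stats::runif(2, -1, 1), A)
    cc <- conic_coefficients_2d(m)
    expect_lt(abs(cc$D), cc$tol)
    expect_identical(cc$conic_class, "degenerate/parabolic")
  }
})

test_that("the discriminant is the perfect square of the interaction contrast", {
  set.seed(13)
  for (case in 1:100) {
    m <- random_model(2)
    a <- m$A
    cc <- conic_coefficients_2d(m)
    ident <- (a[1, 2] * (a[1, 1] - a[2, 1]) - a[2, 1] * (a[2, 2] - a[1, 2]))^2
    expect_lt(abs(cc$D - ident), 1e-12 * (1 + max(abs(cc$q))^2))
    expect_gte(cc$D, 0)  # never elliptic
    # K-invariance of the classification
    cc2 <- conic_coefficients_2d(m, K = 17.3)
    expect_identical(cc2$conic_class, cc$conic_class)
  }
})

test_that("grid sampling brackets the constraint curve's zero set", {
  hc <- constraint_coefficients(wolf_rabbit_model())
  g <- constraint_grid_2d(hc, c(500, 1500), c(40, 120), resolution = 60)
  expect_true(any(g$value > 0) && any(g$value < 0))  # curve crosses window
  at_eq <- g[which.min((g$N1 - 1000)^2 + (g$N2 - 80)^2), ]
  expect_lt(abs(at_eq$value), 0.01)
})
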