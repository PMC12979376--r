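# Model construction, integration, equilibrium and stability.

test_that("model constructor validates shapes and finiteness", {
  expect_s3_class(glv_model(1, matrix(-1, 1, 1)), "glv_model")
  expect_error(glv_model(c(1, 2), matrix(0, 1, 1)), "matrix")
  expect_error(glv_model(c(1, NA), matrix(0, 2, 2)), "finite")
  expect_error(glv_model(1, matrix(Inf, 1, 1)), "finite")
})

test_that("integration matches exponential and logistic closed forms", {
  tr <- integrate_glv(exp_model(1), 1, t_end = 1, dt_out = 0.01)
  expect_equal(unname(tr$N[nrow(tr$N), 1]), exp(1), tolerance = 1e-8)

  tr <- integrate_glv(logistic_model(), 0.5, t_end = 30, dt_out = 0.05)
  expect_equal(unname(tr$N[nrow(tr$N), 1]), 1, tolerance = 1e-7)
  mid <- which.min(abs(tr$t - 3))
  expect_equal(unname(tr$N[mid, 1]), logistic_solution(tr$t[mid], 0.5),
               tolerance = 1e-8)
})

test_that("trajectories stay strictly positive and start at N0", {
  set.seed(11)
  for (s in 1:5) {
    cfg <- generate_fixture("random_stable", s)
    tr <- integrate_glv(cfg$model, cfg$N0, t_end = 10, dt_out = 0.05)
    expect_true(all(tr$N > 0))
    expect_equal(unname(tr$N[1, ]), cfg$N0)
    expect_equal(unname(tr$cumN[1, ]), rep(0, cfg$model$n))
    expect_true(all(diff(tr$cumN) >= 0))
  }
})

test_that("starting at the coexistence equilibrium yields a constant trajectory", {
  wr <- wolf_rabbit_model()
  tr <- integrate_glv(wr, c(1000, 80), t_end = 50, dt_out = 0.5)
  expect_lt(max(abs(t(tr$N) - c(1000, 80)) / c(1000, 80)), 1e-9)
})

test_that("non-positive initial states are a domain error", {
  expect_error(integrate_glv(exp_model(), 0, 1), "positive")
  expect_error(integrate_glv(exp_model(), -1, 1), "positive")
  expect_error(integrate_glv(exp_model(), 1, -2), "t_end")
})

test_that("finite-time blow-up raises a diagnostic carrying the last valid time", {
  # dN/dt = N(1 + N) from N0 = 1 blows up at t = log 2
  m <- glv_model(1, matrix(1, 1, 1))
  err <- tryCatch(integrate_glv(m, 1, t_end = 1, dt_out = 0.01),
                  error = function(e) e)
  expect_s3_class(err, "glvflux_blowup_error")
  expect_true(is.numeric(err$last_time) && err$last_time < 1)
})

test_that("trapezoid running integrals match closed forms", {
  # constant N = 2 on [0, 3]
  m <- glv_model(0, matrix(0, 1, 1))
  tr <- integrate_glv(m, 2, t_end = 3, dt_out = 0.01)
  cum <- cumulative_abundances(tr)
  expect_equal(cum[1], 0)
  expect_equal(unname(cum[nrow(cum), 1]), 6, tolerance = 1e-12)

  # N = e^t on [0, 1]: integral e - 1
  tr <- integrate_glv(exp_model(1), 1, t_end = 1, dt_out = 0.005)
  cum <- cumulative_abundances(tr)
  expect_equal(unname(cum[nrow(cum), 1]), exp(1) - 1, tolerance = 1e-5)
  # solver-carried integrals agree with quadrature to trapezoid order
  expect_equal(unname(tr$cumN[, 1]), unname(cum[, 1]), tolerance = 1e-5)
})

test_that("grid refinement converges: halving dt_out barely moves the terminal state", {
  wr <- wolf_rabbit_model()
  t1 <- integrate_glv(wr, c(1500, 60), 40, dt_out = 0.1)
  t2 <- integrate_glv(wr, c(1500, 60), 40, dt_out = 0.05,
                      rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(t1$N[nrow(t1$N), ] - t2$N[nrow(t2$N), ]) /
                  t2$N[nrow(t2$N), ]), 1e-6)
})

test_that("coexistence equilibrium solves r + A N* = 0 and filters sign/singularity", {
  wr <- wolf_rabbit_model()
  eq <- coexistence_equilibrium(wr)
  expect_equal(unname(eq), c(1000, 80), tolerance = 1e-12)
  expect_lt(max(abs(wr$r + wr$A %*% eq)), 1e-10 * (1 + max(abs(wr$r))))

  # zero growth-rate vector: equilibrium at the origin, not interior
  expect_null(coexistence_equilibrium(glv_model(c(0, 0), diag(-1, 2))))
  # singular interaction matrix
  expect_null(coexistence_equilibrium(glv_model(c(1, 1), matrix(1, 2, 2))))

  # property: r := -A x for random positive x recovers x
  set.seed(21)
  for (case in 1:25) {
    n <- sample(2:4, 1)
    A <- matrix(stats::runif(n * n, -1, 1), n, n)
    if (abs(det(A)) < 1e-3) next
    x <- stats::runif(n, 0.1, 3)
    eq <- coexistence_equilibrium(glv_model(-as.vector(A %*% x), A))
    expect_equal(unname(eq), x, tolerance = 1e-8)
  }
})

test_that("stability classification covers center, node and saddle cases", {
  wr <- wolf_rabbit_model()
  er <- stability_at(wr, c(1000, 80))
  expect_identical(er$classification, "center (linear)")
  expect_equal(sort(Im(er$eigenvalues)), c(-0.2, 0.2), tolerance = 1e-12)
  expect_lt(max(abs(Re(er$eigenvalues))), 1e-12)

  m <- glv_model(c(1, 1), diag(-1, 2))
  er <- stability_at(m, c(1, 1))
  expect_identical(er$classification, "stable node")
  expect_equal(sort(Re(er$eigenvalues)), c(-1, -1))

  er <- stability_at(logistic_model(), 1)
  expect_identical(er$classification, "stable node")
  expect_equal(Re(er$eigenvalues), -1)

  # saddle: competitive exclusion pair
  ms <- glv_model(c(1, 1), matrix(c(-1, -2, -2, -1), 2, 2))
  expect_identical(stability_at(ms, c(1/3, 1/3))$classification, "saddle")

  expect_error(stability_at(wr, c(-1, 80)), "positive")
})

test_that("model JSON and trajectory CSV round-trip at full precision", {
  wr <- wolf_rabbit_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_glv_model(wr, f)
  back <- read_glv_model(f)
  expect_equal(back$r, wr$r)
  expect_equal(back$A, wr$A, ignore_attr = TRUE)
  expect_identical(back$labels, wr$labels)

  tr <- integrate_glv(wr, c(1500, 60), 5, dt_out = 0.5)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, csv)
  got <- utils::read.csv(csv)
  expect_identical(names(got), c("t", "N_1", "N_2", "cum_1", "cum_2"))
  expect_identical(got$N_1, unname(tr$N[, 1]))  # repr round-trip, bitwise
  expect_identical(got$cum_2, unname(tr$cumN[, 2]))
})
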