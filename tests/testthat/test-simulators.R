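test_that("benchmark systems carry the documented true parameters", {
  expect_equal(benchmark_system("lorenz")$params,
               list(sigma = 10, rho = 28, beta = 3))
  expect_equal(benchmark_system("lotka_volterra")$params,
               list(alpha = 1, beta = 0.2, delta = 0.1, gamma = 0.2))
  mg <- benchmark_system("maglev")$params
  expect_equal(mg[c("C", "L", "R")], list(C = 1.5, L = 3, R = 6))
  expect_equal(benchmark_system("rossler")$params,
               list(a = 0.1, b = 0.1, c = 14))
  expect_equal(benchmark_system("msd")$params, list(m = 1, k = 84, b = 0.9))
  # overrides replace named values, unknown keys are rejected
  expect_equal(benchmark_system("msd", list(k = 50))$params$k, 50)
  expect_error(benchmark_system("msd", list(zeta = 1)), "unknown parameter")
  expect_error(benchmark_system("unknown"), "arg")
})

test_that("a single Euler step of the Lorenz system matches hand evaluation", {
  # f(-8, 7, 27) = (150, -15, -137), so x + 0.001 f = (-7.85, 6.985, 26.863)
  sys <- benchmark_system("lorenz")
  ts <- simulate_system(sys, x0 = c(-8, 7, 27), dt = 0.001, n_steps = 1,
                        integrator = "euler")
  expect_equal(unname(ts$Y[2, ]), c(-7.85, 6.985, 26.863), tolerance = 1e-12)
})

test_that("equilibria and zero dynamics stay constant", {
  # Lotka-Volterra equilibrium (gamma/delta, alpha/beta) = (2, 5)
  sys <- benchmark_system("lotka_volterra")
  ts <- simulate_system(sys, x0 = c(2, 5), dt = 0.01, n_steps = 100)
  expect_equal(max(abs(sweep(ts$Y, 2, c(2, 5)))), 0, tolerance = 1e-10)

  # undriven linear control system from the origin stays at the origin
  lc <- benchmark_system("linear_control")
  ts2 <- simulate_system(lc, x0 = c(0, 0), input = make_input("zero"),
                         dt = 0.001, n_steps = 100)
  expect_equal(max(abs(ts2$Y)), 0)
})

test_that("maglev guard reports a position zero crossing", {
  sys <- benchmark_system("maglev", list(g = -100))  # forced downwards
  expect_error(simulate_system(sys, x0 = c(0.1, 0, 1), dt = 0.01,
                               n_steps = 500,
                               input = make_input("constant", offset = 0)),
               "position crossed zero")
})

test_that("input signals evaluate per their definition", {
  expect_equal(eval_input(make_input("constant", offset = 1), 0.5), 1)
  expect_equal(eval_input(make_input("sinusoid", amplitude = 1, frequency = 1),
                          0.25), 1)
  expect_equal(eval_input(make_input("sinusoid", amplitude = 0, offset = 3),
                          c(0, 1, 2)), rep(3, 3))
  expect_equal(eval_input(make_input("zero"), 1:5), rep(0, 5))
  expect_error(make_input("sinusoid", frequency = -1), "frequency")
})

test_that("measurement noise is reproducible, unbiased and sized correctly", {
  sys <- benchmark_system("msd")
  ts <- simulate_system(sys, dt = 0.001, n_steps = 1000)
  # sd = 0 is the identity
  expect_identical(add_measurement_noise(ts, noise_spec(0, seed = 1))$Y, ts$Y)
  # fixed seed: bit-identical injections
  a <- add_measurement_noise(ts, noise_spec(1, seed = 7))
  b <- add_measurement_noise(ts, noise_spec(1, seed = 7))
  expect_identical(a$Y, b$Y)
  expect_false(identical(a$Y, add_measurement_noise(ts, noise_spec(1, 8))$Y))
  expect_error(noise_spec(-1), "sd")
  # empirical sd within 1% of 1 at N = 1e5 (per channel)
  N <- 100000
  big <- time_series((0:(N - 1)) * 0.01, matrix(0, N, 1))
  noisy <- add_measurement_noise(big, noise_spec(1, seed = 9))
  expect_equal(stats::sd(noisy$Y[, 1]), 1, tolerance = 0.01)
})

test_that("noise covariance matches diag(sd^2) within sampling error", {
  N <- 100000
  base <- time_series((0:(N - 1)) * 0.01, matrix(0, N, 2))
  noisy <- add_measurement_noise(base, noise_spec(c(1, 0.5), seed = 10))
  S <- stats::cov(noisy$Y)
  # chi-square-style bound on the variances at n = 1e5 (~1% rel.)
  expect_equal(S[1, 1], 1, tolerance = 0.02)
  expect_equal(S[2, 2], 0.25, tolerance = 0.02)
  expect_lt(abs(S[1, 2]) / sqrt(S[1, 1] * S[2, 2]), 0.02)
})

test_that("exact-Euler fixtures satisfy the discrete model identically", {
  lib <- benchmark_library("msd")
  # zero parameters: constant trajectory
  ts0 <- euler_fixture(lib, rep(0, 10), x0 = c(1, 2), dt = 0.001, n_steps = 50)
  expect_equal(max(abs(sweep(ts0$Y, 2, c(1, 2)))), 0)

  # discrete MSD parameters: x(k+1) - x(k) == Psi(k) theta at every k
  th <- c(0, 0.001, 0, 0, 0, -0.084, -0.0009, 0, 0, 0)
  ts <- euler_fixture(lib, th, x0 = c(10, 0), dt = 0.001, n_steps = 200)
  for (k in c(1, 57, 200)) {
    inc <- ts$Y[k + 1, ] - ts$Y[k, ]
    expect_equal(inc, as.numeric(build_psi(lib, ts$Y[k, ]) %*% th),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # regeneration is bit-identical
  ts2 <- euler_fixture(lib, th, x0 = c(10, 0), dt = 0.001, n_steps = 200)
  expect_identical(ts$Y, ts2$Y)
})

test_that("rk4 and euler agree at small steps on Lotka-Volterra", {
  sys <- benchmark_system("lotka_volterra")
  a <- simulate_system(sys, x0 = c(1, 1), dt = 1e-4, n_steps = 10000,
                       integrator = "rk4")
  b <- simulate_system(sys, x0 = c(1, 1), dt = 1e-4, n_steps = 10000,
                       integrator = "euler")
  rel <- max(abs(a$Y - b$Y)) / max(abs(a$Y))
  expect_lt(rel, 1e-3)
})

test_that("undamped oscillator conserves energy under rk4", {
  sys <- benchmark_system("msd", list(b = 0))
  ts <- simulate_system(sys, x0 = c(1, 0), dt = 1e-4, n_steps = 100000,
                        integrator = "rk4")
  E <- 0.5 * 1 * ts$Y[, 2]^2 + 0.5 * 84 * ts$Y[, 1]^2
  expect_lt(max(abs(E - E[1])) / E[1], 1e-3)
})

test_that("true_parameters places coefficients at the right indices", {
  lib <- benchmark_library("lorenz")
  th <- true_parameters("lorenz", lib, dt = 0.001)
  # sigma sits on th2 (y1, eq 1) and th3 (y2, eq 1); rho on th12; beta on th24
  expect_equal(th[2], -10 * 0.001)
  expect_equal(th[3], 10 * 0.001)
  expect_equal(th[12], 28 * 0.001)
  expect_equal(th[24], -3 * 0.001)
  expect_equal(sum(th != 0), 7)
  # a library missing a dynamic term is rejected
  lin <- make_polynomial_library(3, degree = 1, include_constant = FALSE)
  expect_error(true_parameters("lorenz", lin, 0.001), "lacks term")
})

test_that("time_series validates its sampling grid", {
  expect_error(time_series(c(0, 1, 1, 2), matrix(0, 4, 1)),
               "strictly increasing")
  expect_error(time_series(c(0, 1, 2, 3.5), matrix(0, 4, 1)), "non-uniform")
  expect_error(time_series(0:3, matrix(0, 3, 1)), "lengths differ")
})
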