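test_that("initialisation applies defaults and policies", {
  cfg <- observer_config()
  st <- init_observer(cfg, n = 2, r = 10, first_measurement = c(1, 2))
  expect_equal(st$Px, diag(0.1, 2))
  expect_equal(st$Ptheta, diag(0.1, 10))
  expect_equal(st$Gamma, matrix(0, 2, 10))
  expect_equal(st$x_hat, c(1, 2))       # first-measurement policy
  expect_equal(st$theta_hat, rep(0, 10))
  expect_equal(st$k, 0L)

  st2 <- init_observer(observer_config(x0_policy = "zeros"), 3, 5)
  expect_equal(st2$x_hat, c(0, 0, 0))
  st3 <- init_observer(observer_config(x0_policy = "explicit", x0 = c(5, 1, 1)),
                       3, 5)
  expect_equal(st3$x_hat, c(5, 1, 1))
})

test_that("configuration validation rejects bad tunings", {
  expect_error(observer_config(lambda_x = 1.5), "\\(0, 1\\]")
  expect_error(observer_config(lambda_theta = 0), "\\(0, 1\\]")
  expect_error(observer_config(Rx = -1), "positive")
  bad <- matrix(c(1, 2, 3, 4), 2)            # not symmetric
  expect_error(observer_config(Px0 = bad), "symmetric")
  neg <- diag(c(1, -1))                      # not positive definite
  expect_error(observer_config(Rtheta = neg), "positive definite")
  expect_error(init_observer(observer_config(Px0 = diag(3),
                                             x0_policy = "zeros"),
                             n = 2, r = 4),
               "dimension")
})

test_that("scalar gain algebra matches direct evaluation", {
  # n = r = 1, Px = 0.1, Rx = 1, Gamma = 0, Ptheta = 0.1, Rtheta = 1:
  # Kx = 0.1/1.1 = 1/11, Omega = 1, Ktheta = 0, Gamma_post = 0
  cfg <- observer_config(Rx = 1, Rtheta = 1, Px0 = 0.1, Ptheta0 = 0.1)
  st <- compute_gains(init_observer(cfg, 1, 1, first_measurement = 0))
  expect_equal(st$scratch$Kx[1, 1], 1 / 11)
  expect_equal(st$scratch$Omega[1, 1], 1)
  expect_equal(st$scratch$Ktheta[1, 1], 0)
  expect_equal(st$scratch$Gamma_post[1, 1], 0)

  # the scalar measurement update: x <- 0 + (1/11) * 1.1 = 0.1
  st <- measurement_update(st, y = 1.1)
  expect_equal(st$x_hat, 0.1)
  expect_equal(st$theta_hat, 0)
})

test_that("zero sensitivity keeps the parameter estimate frozen", {
  cfg <- observer_config()
  st <- init_observer(cfg, 3, 7, first_measurement = c(1, 2, 3))
  st <- compute_gains(st)
  expect_equal(st$scratch$Ktheta, matrix(0, 7, 3))
  expect_equal(st$scratch$Gamma_post, matrix(0, 3, 7))
  st <- measurement_update(st, c(4, 5, 6))
  expect_equal(st$theta_hat, rep(0, 7))
})

test_that("gains match a dense explicit-inverse reference on random SPD input", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 2; r <- 3
    Px <- random_spd(n); Pt <- random_spd(r)
    Rx <- random_spd(n); Rt <- random_spd(n)
    G <- matrix(stats::rnorm(n * r), n)
    cfg <- observer_config(Rx = Rx, Rtheta = Rt, Px0 = Px, Ptheta0 = Pt,
                           Gamma0 = G, x0_policy = "zeros")
    st <- compute_gains(init_observer(cfg, n, r))
    ref <- ref_observer_step(numeric(n), numeric(r), Px, Pt, G,
                             y = stats::rnorm(n), Psi = matrix(0, n, r),
                             Rx, Rt, 0.995, 0.999)
    expect_equal(st$scratch$Kx, ref$Kx, tolerance = 1e-12)
    expect_equal(st$scratch$Omega, ref$Omega, tolerance = 1e-12)
    expect_equal(st$scratch$Ktheta, ref$Kt, tolerance = 1e-12)
    expect_equal(st$scratch$Gamma_post, ref$G_post, tolerance = 1e-12)
  }
})

test_that("measurement update is inert on zero innovation", {
  cfg <- observer_config(Gamma0 = matrix(1, 2, 4))
  st <- init_observer(cfg, 2, 4, first_measurement = c(1, -1))
  st <- compute_gains(st)
  st2 <- measurement_update(st, c(1, -1))    # e = 0
  expect_equal(st2$x_hat, st$x_hat)
  expect_equal(st2$theta_hat, st$theta_hat)
  expect_error(measurement_update(st, c(1, 2, 3)), "length")
})

test_that("prediction update propagates, inflates and shifts as specified", {
  cfg <- observer_config(lambda_x = 1, lambda_theta = 0.999)
  lib <- benchmark_library("msd")
  st <- init_observer(cfg, 2, 10, first_measurement = c(1, 2))
  st <- compute_gains(st)
  st <- measurement_update(st, c(1, 2))
  G_meas <- st$Gamma
  x_meas <- st$x_hat

  # Psi = 0: state propagates unchanged and Gamma(k+1|k) = Gamma(k|k)
  st0 <- prediction_update(st, matrix(0, 2, 10), cfg)
  expect_equal(st0$x_hat, x_meas)
  expect_equal(st0$Gamma, G_meas)
  expect_equal(st0$k, 1L)

  # with Gamma = 0 we have Ktheta = 0, so Ptheta strictly inflates by
  # 1/lambda_theta while Px is untouched at lambda_x = 1, Kx fixed
  expect_equal(st0$Ptheta, diag(0.1 / 0.999, 10))
  Kx <- st$scratch$Kx
  expect_equal(st0$Px, (diag(2) - Kx) %*% diag(0.1, 2), tolerance = 1e-14)
  expect_error(prediction_update(st, matrix(0, 2, 3), cfg), "dimensions")
})

test_that("a zero library never moves the parameter estimate", {
  # all terms present but Psi == 0 along the trajectory is equivalent to
  # an absent library: Gamma stays 0, hence Ktheta stays 0
  cfg <- observer_config()
  lib <- benchmark_library("msd")
  st <- init_observer(cfg, 2, 10, first_measurement = c(0, 0))
  for (k in 1:20)
    st <- observer_step(st, c(0, 0), numeric(), lib, cfg)  # y = 0 => Psi = 0
  expect_equal(st$theta_hat, rep(0, 10))
  expect_equal(st$Gamma, matrix(0, 2, 10))
})

test_that("one full step reproduces the straight-line reference transcription", {
  set.seed(33)
  lib <- benchmark_library("msd")
  cfg <- observer_config(Gamma0 = matrix(stats::rnorm(20), 2))
  st <- init_observer(cfg, 2, 10, first_measurement = c(1, -2))
  st$theta_hat <- stats::rnorm(10)
  y <- c(0.9, -1.8)
  ref <- ref_observer_step(st$x_hat, st$theta_hat, st$Px, st$Ptheta, st$Gamma,
                           y, build_psi(lib, y), st$Rx, st$Rtheta,
                           cfg$lambda_x, cfg$lambda_theta)
  st2 <- observer_step(st, y, numeric(), lib, cfg)
  expect_equal(st2$x_hat, ref$x, tolerance = 1e-12)
  expect_equal(st2$theta_hat, ref$th, tolerance = 1e-12)
  expect_equal(st2$Px, (ref$Px + t(ref$Px)) / 2, tolerance = 1e-12)
  expect_equal(st2$Ptheta, (ref$Pt + t(ref$Pt)) / 2, tolerance = 1e-12)
  expect_equal(st2$Gamma, ref$G, tolerance = 1e-12)
})

test_that("one-step-ahead prediction error vanishes on exact-model data", {
  lib <- benchmark_library("msd")
  th <- true_parameters("msd", lib, dt = 0.01)
  ts <- euler_fixture(lib, th, x0 = c(10, 0), dt = 0.01, n_steps = 300)
  cfg <- noisefree_config()
  st <- init_observer(cfg, 2, 10, first_measurement = ts$Y[1, ])
  pred_err <- numeric(300)
  for (k in 1:300) {
    st <- observer_step(st, ts$Y[k, ], numeric(), lib, cfg)
    pred_err[k] <- sqrt(sum((ts$Y[k + 1, ] - st$x_hat)^2))
  }
  expect_lt(pred_err[300], 1e-8)
  expect_lt(mean(tail(pred_err, 50)), mean(head(pred_err, 50)))
})

test_that("covariance matrices stay SPD under sustained random excitation", {
  set.seed(55)
  cfg <- observer_config()
  lib <- make_polynomial_library(2, degree = 2, include_constant = FALSE)
  st <- init_observer(cfg, 2, lib$r, first_measurement = c(0, 0))
  min_px <- min_pt <- Inf
  for (k in 1:5000) {
    st <- observer_step(st, stats::rnorm(2), numeric(), lib, cfg)
    if (k %% 100 == 0) {
      min_px <- min(min_px, min(eigen(st$Px, TRUE, TRUE)$values))
      min_pt <- min(min_pt, min(eigen(st$Ptheta, TRUE, TRUE)$values))
    }
  }
  expect_gt(min_px, 0)
  expect_gt(min_pt, 0)
  expect_equal(st$Px, t(st$Px))
  expect_equal(st$Ptheta, t(st$Ptheta))

  # long-horizon batch run on random measurements: the final matrices
  # must still admit a Cholesky factorisation
  set.seed(56)
  N <- 100000
  ts <- time_series((0:(N - 1)) * 0.01, matrix(stats::rnorm(N * 2), ncol = 2))
  tr <- run_discovery(ts, lib, cfg)
  expect_silent(chol(tr$state$Px))
  expect_silent(chol(tr$state$Ptheta))
  expect_true(all(is.finite(tr$theta_path)))
})
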