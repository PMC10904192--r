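#' Benchmark dynamical systems
#'
#' Returns one of the bundled continuous-time benchmark systems with its
#' default ("true") parameters:
#' \describe{
#'   \item{msd}{mass-spring-damper, states (position, velocity);
#'     m = 1 kg, k = 84 N/m, b = 0.9 Ns/m.}
#'   \item{lorenz}{chaotic Lorenz system; sigma = 10, rho = 28, beta = 3,
#'     default x0 = (-8, 7, 27).}
#'   \item{rossler}{Roessler attractor; a = 0.1, b = 0.1, c = 14.}
#'   \item{lotka_volterra}{predator-prey equations; alpha = 1, beta = 0.2,
#'     delta = 0.1, gamma = 0.2.}
#'   \item{van_der_pol}{Van der Pol oscillator; mu = 2.}
#'   \item{linear_control}{2-state driven linear system with
#'     A = rbind(c(-10, 20), c(-0.4, -2)), B = c(0, 2).}
#'   \item{maglev}{magnetic levitation model, states (position, velocity,
#'     current); C = 1.5, L = 3, R = 6, g = 9.81, m = 1,
#'     default x0 = (5, 1, 1).}
#' }
#'
#' @param name system name.
#' @param overrides named list replacing default parameter values.
#' @return an object of class `odisco_system` with fields `name`,
#'   `n_states`, `n_inputs`, `rhs(x, u, params)`, `params`, `default_x0`,
#'   and an optional `state_guard` used to detect invalid states during
#'   integration.
#' @examples
#' sys <- benchmark_system("lorenz")
#' sys$params$sigma
#' @export
benchmark_system <- function(name, overrides = list()) {
  name <- match.arg(name, c("msd", "lorenz", "rossler", "lotka_volterra",
                            "van_der_pol", "linear_control", "maglev"))
  def <- switch(name,
    msd = list(
      n_states = 2, n_inputs = 0,
      params = list(m = 1, k = 84, b = 0.9),
      default_x0 = c(10, 0),
      rhs = function(x, u, p) c(x[2], -(p$k / p$m) * x[1] - (p$b / p$m) * x[2])),
    lorenz = list(
      n_states = 3, n_inputs = 0,
      params = list(sigma = 10, rho = 28, beta = 3),
      default_x0 = c(-8, 7, 27),
      rhs = function(x, u, p) c(p$sigma * (x[2] - x[1]),
                                x[1] * (p$rho - x[3]) - x[2],
                                x[1] * x[2] - p$beta * x[3])),
    rossler = list(
      n_states = 3, n_inputs = 0,
      params = list(a = 0.1, b = 0.1, c = 14),
      default_x0 = c(1, 1, 1),
      rhs = function(x, u, p) c(-x[2] - x[3],
                                x[1] + p$a * x[2],
                                p$b + x[3] * (x[1] - p$c))),
    lotka_volterra = list(
      n_states = 2, n_inputs = 0,
      params = list(alpha = 1, beta = 0.2, delta = 0.1, gamma = 0.2),
      default_x0 = c(1, 1),
      rhs = function(x, u, p) c(p$alpha * x[1] - p$beta * x[1] * x[2],
                                p$delta * x[1] * x[2] - p$gamma * x[2])),
    van_der_pol = list(
      n_states = 2, n_inputs = 0,
      params = list(mu = 2),
      default_x0 = c(2, 0),
      rhs = function(x, u, p) c(x[2],
                                p$mu * (1 - x[1]^2) * x[2] - x[1])),
    linear_control = list(
      n_states = 2, n_inputs = 1,
      params = list(a11 = -10, a12 = 20, a21 = -0.4, a22 = -2, b1 = 0, b2 = 2),
      default_x0 = c(0, 0),
      rhs = function(x, u, p) c(p$a11 * x[1] + p$a12 * x[2] + p$b1 * u[1],
                                p$a21 * x[1] + p$a22 * x[2] + p$b2 * u[1])),
    maglev = list(
      n_states = 3, n_inputs = 1,
      params = list(C = 1.5, L = 3, R = 6, g = 9.81, m = 1),
      default_x0 = c(5, 1, 1),
      rhs = function(x, u, p) c(x[2],
                                p$g - (p$C / p$m) * (x[3] / x[1])^2,
                                -(p$R / p$L) * x[3] + u[1] / p$L),
      state_guard = function(x) {
        if (x[1] <= 0) "position crossed zero (rational term blow-up)" else NULL
      }))
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(def$params))
    if (length(unknown))
      stop("unknown parameter(s) for ", name, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    def$params[names(overrides)] <- overrides
  }
  structure(c(list(name = name), def), class = "odisco_system")
}

#' @export
print.odisco_system <- function(x, ...) {
  cat("<system> ", x$name, ": ", x$n_states, " states, ", x$n_inputs,
      " inputs\n  params: ",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Deterministic input signals
#'
#' @param kind `"zero"`, `"constant"` or `"sinusoid"`.
#' @param amplitude,frequency,offset,phase sinusoid
#'   `u(t) = offset + amplitude * sin(2*pi*frequency*t + phase)`
#'   (frequency in Hz, phase in radians); a constant signal evaluates to
#'   `offset`.
#' @return an object of class `input_signal`; evaluate with
#'   [eval_input()].
#' @export
make_input <- function(kind = c("zero", "constant", "sinusoid"),
                       amplitude = 0, frequency = 0, offset = 0, phase = 0) {
  kind <- match.arg(kind)
  if (frequency < 0) stop("frequency must be >= 0", call. = FALSE)
  structure(list(kind = kind, amplitude = amplitude, frequency = frequency,
                 offset = offset, phase = phase), class = "input_signal")
}

#' Evaluate an input signal
#'
#' @param input an `input_signal`.
#' @param t time (scalar or vector, seconds).
#' @return numeric vector of input values.
#' @export
eval_input <- function(input, t) {
  stopifnot(inherits(input, "input_signal"))
  switch(input$kind,
    zero = rep.int(0, length(t)),
    constant = rep.int(input$offset, length(t)),
    sinusoid = input$offset +
      input$amplitude * sin(2 * pi * input$frequency * t + input$phase))
}

#' Uniformly sampled multivariate time series
#'
#' Container for measurements of a dynamical system: a strictly
#' increasing, uniformly spaced time grid `t`, an N x n measurement
#' matrix `Y` (columns `y1..yn`), an optional N x p input matrix `U`,
#' and a provenance list `meta`.
#'
#' @param t time stamps (seconds).
#' @param Y numeric matrix (or vector for n = 1), samples in rows.
#' @param U optional numeric input matrix, samples in rows.
#' @param meta named list of provenance (system, params, noise sd, seed,
#'   integrator, ...).
#' @param tol relative tolerance on uniform spacing.
#' @return an object of class `time_series`.
#' @export
time_series <- function(t, Y, U = NULL, meta = list(), tol = 1e-9) {
  Y <- as.matrix(Y)
  if (!is.null(U)) U <- as.matrix(U)
  N <- length(t)
  if (nrow(Y) != N) stop("Y and t lengths differ", call. = FALSE)
  if (!is.null(U) && nrow(U) != N) stop("U and t lengths differ", call. = FALSE)
  if (N < 2) stop("need at least two samples", call. = FALSE)
  d <- diff(t)
  bad <- which(d <= 0)
  if (length(bad))
    stop("timestamps not strictly increasing at index ", bad[1] + 1, call. = FALSE)
  dt <- stats::median(d)
  off <- which(abs(d - dt) > tol * dt)
  if (length(off))
    stop("non-uniform sampling at index ", off[1] + 1,
         " (dt = ", format(d[off[1]]), ", expected ", format(dt), ")",
         call. = FALSE)
  colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  if (!is.null(U) && ncol(U) > 0) colnames(U) <- paste0("u", seq_len(ncol(U)))
  structure(list(t = as.numeric(t), Y = Y, U = U, dt = dt, meta = meta),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat("<time_series> N=", length(x$t), " states=", ncol(x$Y),
      " inputs=", if (is.null(x$U)) 0 else ncol(x$U),
      " dt=", format(x$dt), "s span=[", format(x$t[1]), ", ",
      format(x$t[length(x$t)]), "]s\n", sep = "")
  if (!is.null(x$meta$system)) cat("  system:", x$meta$system, "\n")
  invisible(x)
}

#' Simulate a benchmark system
#'
#' Integrates the continuous-time dynamics with a fixed-step solver
#' (classical Runge-Kutta by default) and samples the noise-free states
#' at the requested interval. Divergence (non-finite states) and invalid
#' states (e.g. the magnetic-levitation position crossing zero) abort
#' with the offending step index.
#'
#' @param system an `odisco_system`.
#' @param x0 initial state (defaults to the system's `default_x0`).
#' @param input an `input_signal` (default zero).
#' @param dt sampling interval (s).
#' @param n_steps number of steps; the series has `n_steps + 1` samples.
#' @param integrator `"rk4"` or `"euler"`.
#' @return a [time_series()] of noise-free states (and evaluated inputs
#'   when the system is driven).
#' @export
simulate_system <- function(system, x0 = NULL, input = make_input("zero"),
                            dt, n_steps, integrator = c("rk4", "euler")) {
  stopifnot(inherits(system, "odisco_system"), dt > 0, n_steps >= 1)
  integrator <- match.arg(integrator)
  if (is.null(x0)) x0 <- system$default_x0
  if (length(x0) != system$n_states) stop("x0 has wrong length", call. = FALSE)
  times <- (0:n_steps) * dt
  func <- function(t, x, parms)
    list(system$rhs(x, eval_input(input, t), system$params))
  out <- deSolve::ode(y = as.numeric(x0), times = times, func = func,
                      parms = NULL, method = integrator)
  Y <- unname(out[, -1, drop = FALSE])
  bad <- which(rowSums(!is.finite(Y)) > 0)
  if (length(bad))
    stop("trajectory diverged (non-finite state) at step ", bad[1] - 1,
         call. = FALSE)
  if (!is.null(system$state_guard)) {
    for (i in seq_len(nrow(Y))) {
      msg <- system$state_guard(Y[i, ])
      if (!is.null(msg)) stop(msg, " at step ", i - 1, call. = FALSE)
    }
  }
  U <- if (system$n_inputs > 0) matrix(eval_input(input, times), ncol = 1)
       else NULL
  time_series(times, Y, U,
              meta = list(system = system$name, params = system$params,
                          x0 = as.numeric(x0), integrator = integrator,
                          dt = dt, input = unclass(input), noise_sd = 0))
}

#' Gaussian measurement-noise specification
#'
#' @param sd per-channel standard deviation (scalar recycled, or one
#'   value per state), in the units of the state.
#' @param seed integer seed making the injection reproducible.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(sd, seed = NULL) {
  if (any(sd < 0)) stop("noise sd must be >= 0", call. = FALSE)
  structure(list(sd = sd, seed = seed), class = "noise_spec")
}

#' Add sensor noise to a time series
#'
#' Adds independent zero-mean Gaussian noise per channel and per sample,
#' modelling `y(k) = x(k) + v(k)` with `v(k) ~ N(0, diag(sd^2))`.
#' With a fixed seed the output is bit-identical across calls; `sd = 0`
#' is the identity.
#'
#' @param ts a [time_series()].
#' @param noise a [noise_spec()].
#' @return the noisy `time_series` (meta records sd and seed).
#' @export
add_measurement_noise <- function(ts, noise) {
  stopifnot(inherits(ts, "time_series"), inherits(noise, "noise_spec"))
  n <- ncol(ts$Y)
  sd <- rep_len(noise$sd, n)
  if (!is.null(noise$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
           else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(noise$seed)
  }
  N <- nrow(ts$Y)
  V <- vapply(seq_len(n), function(j) stats::rnorm(N, 0, sd[j]), numeric(N))
  ts$Y <- ts$Y + V
  colnames(ts$Y) <- paste0("y", seq_len(n))
  ts$meta$noise_sd <- sd
  ts$meta$noise_seed <- noise$seed
  ts
}

#' Exact discrete-time fixture trajectory
#'
#' Iterates the discrete approximation model
#' `x(k+1) = x(k) + Psi(x(k), u(k)) theta` exactly (no continuous-time
#' integration, no noise), so the observer's modelling error on the
#' resulting data is identically zero. Used by the identity and exact
#' recovery test suites.
#'
#' @param lib an `odisco_library`.
#' @param theta_true parameter vector of length `lib$r` (discrete scale,
#'   i.e. `dt` times the continuous coefficients).
#' @param x0 initial state.
#' @param dt nominal sampling interval recorded on the time axis.
#' @param n_steps number of iterations; the series has `n_steps + 1`
#'   samples.
#' @param input an `input_signal`.
#' @return a [time_series()] whose meta records `theta_true`.
#' @export
euler_fixture <- function(lib, theta_true, x0, dt, n_steps,
                          input = make_input("zero")) {
  stopifnot(inherits(lib, "odisco_library"), dt > 0, n_steps >= 1)
  if (length(theta_true) != lib$r)
    stop("theta_true must have length r = ", lib$r, call. = FALSE)
  if (length(x0) != lib$n_states) stop("x0 has wrong length", call. = FALSE)
  n <- lib$n_states
  times <- (0:n_steps) * dt
  uvals <- eval_input(input, times)
  X <- matrix(0, n_steps + 1, n)
  X[1, ] <- as.numeric(x0)
  for (k in seq_len(n_steps)) {
    u <- if (lib$n_inputs > 0) uvals[k] else numeric()
    x_next <- X[k, ] + as.numeric(build_psi(lib, X[k, ], u) %*% theta_true)
    if (any(!is.finite(x_next)))
      stop("fixture diverged at step ", k, call. = FALSE)
    X[k + 1, ] <- x_next
  }
  U <- if (lib$n_inputs > 0) matrix(uvals, ncol = 1) else NULL
  time_series(times, X, U,
              meta = list(system = "euler_fixture", theta_true = theta_true,
                          integrator = "exact_euler", dt = dt,
                          input = unclass(input), noise_sd = 0))
}

#' True library coefficients of a benchmark system
#'
#' Maps the continuous-time right-hand side of a benchmark system onto a
#' candidate library: the discrete-scale true parameter vector has
#' `theta[i] = dt * c(row_i, label_i)` where `c` is the continuous
#' coefficient of the placed term in that state equation (zero for terms
#' absent from the dynamics).
#'
#' @param name benchmark system name (see [benchmark_system()]).
#' @param lib the library the coefficients are expressed in.
#' @param dt sampling interval used for the Euler bridge.
#' @param overrides parameter overrides passed to [benchmark_system()].
#' @return numeric vector of length `lib$r`.
#' @export
true_parameters <- function(name, lib, dt, overrides = list()) {
  sys <- benchmark_system(name, overrides)
  p <- sys$params
  coef <- switch(name,
    msd = list(
      `1` = c(y2 = 1),
      `2` = c(y1 = -p$k / p$m, y2 = -p$b / p$m)),
    lorenz = list(
      `1` = c(y1 = -p$sigma, y2 = p$sigma),
      `2` = c(y1 = p$rho, y2 = -1, `y1*y3` = -1),
      `3` = c(y3 = -p$beta, `y1*y2` = 1)),
    rossler = list(
      `1` = c(y2 = -1, y3 = -1),
      `2` = c(y1 = 1, y2 = p$a),
      `3` = c(`1` = p$b, y3 = -p$c, `y1*y3` = 1)),
    lotka_volterra = list(
      `1` = c(y1 = p$alpha, `y1*y2` = -p$beta),
      `2` = c(y2 = -p$gamma, `y1*y2` = p$delta)),
    van_der_pol = list(
      `1` = c(y2 = 1),
      `2` = c(y1 = -1, y2 = p$mu, `y1^2*y2` = -p$mu)),
    linear_control = list(
      `1` = c(y1 = p$a11, y2 = p$a12, u = p$b1),
      `2` = c(y1 = p$a21, y2 = p$a22, u = p$b2)),
    maglev = list(
      `1` = c(y2 = 1),
      `2` = c(`1` = p$g, `(y3/y1)^2` = -p$C / p$m),
      `3` = c(y3 = -p$R / p$L, u = 1 / p$L)),
    stop("unknown system '", name, "'", call. = FALSE))
  if (lib$n_states != length(coef))
    stop("library has ", lib$n_states, " states but system '", name,
         "' has ", length(coef), call. = FALSE)
  theta <- numeric(lib$r)
  for (i in seq_len(lib$r)) {
    cm <- coef[[as.character(lib$row[i])]]
    v <- cm[lib$labels[i]]
    if (!is.na(v)) theta[i] <- dt * v
  }
  # every dynamic term must be representable in the library
  for (j in seq_along(coef)) {
    missing <- setdiff(names(coef[[j]]),
                       lib$labels[lib$row == j])
    if (length(missing))
      stop("library lacks term(s) ", paste(missing, collapse = ", "),
           " in equation ", j, " of '", name, "'", call. = FALSE)
  }
  theta
}
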