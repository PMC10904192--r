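#' Observer tuning configuration
#'
#' Tuning of the recursive joint state/parameter estimator. Defaults are
#' the benchmark tuning used throughout the bundled studies:
#' \eqn{\lambda_x = 0.995}, \eqn{\lambda_\theta = 0.999},
#' \eqn{R_x = R_\theta = I}, \eqn{P_x(0) = P_\theta(0) = 0.1 I},
#' \eqn{\Gamma(0) = 0}, \eqn{\bar\theta(0) = 0}, and the state estimate
#' initialised from the first measurement.
#'
#' `Rx`, `Rtheta`, `Px0`, `Ptheta0` may be given as positive scalars
#' (expanded to scale * identity once dimensions are known) or as full
#' symmetric positive-definite matrices.
#'
#' @param lambda_x,lambda_theta forgetting factors in (0, 1]; 1 is the
#'   no-forgetting boundary, admitted for diagnostics.
#' @param Rx,Rtheta n x n SPD tuning matrices (or scalar scales).
#' @param Px0 initial n x n state covariance-like matrix (or scale).
#' @param Ptheta0 initial r x r parameter covariance-like matrix (or scale).
#' @param x0_policy `"first_measurement"`, `"zeros"` or `"explicit"`.
#' @param x0 explicit initial state estimate (with `x0_policy = "explicit"`).
#' @param theta0 initial parameter estimate (default zeros).
#' @param Gamma0 initial n x r sensitivity matrix (default zero matrix).
#' @return an object of class `observer_config`.
#' @export
observer_config <- function(lambda_x = 0.995, lambda_theta = 0.999,
                            Rx = 1, Rtheta = 1, Px0 = 0.1, Ptheta0 = 0.1,
                            x0_policy = c("first_measurement", "zeros",
                                          "explicit"),
                            x0 = NULL, theta0 = NULL, Gamma0 = NULL) {
  x0_policy <- match.arg(x0_policy)
  chk_lambda <- function(l, nm) {
    if (!is.numeric(l) || length(l) != 1 || l <= 0 || l > 1)
      stop(nm, " must lie in (0, 1]", call. = FALSE)
  }
  chk_lambda(lambda_x, "lambda_x"); chk_lambda(lambda_theta, "lambda_theta")
  chk_scale <- function(m, nm) {
    if (is.matrix(m)) .check_spd(m, nm)
    else if (!is.numeric(m) || length(m) != 1 || m <= 0)
      stop(nm, " must be a positive scale or an SPD matrix", call. = FALSE)
  }
  chk_scale(Rx, "Rx"); chk_scale(Rtheta, "Rtheta")
  chk_scale(Px0, "Px0"); chk_scale(Ptheta0, "Ptheta0")
  if (x0_policy == "explicit" && is.null(x0))
    stop("x0_policy = 'explicit' requires x0", call. = FALSE)
  structure(list(lambda_x = lambda_x, lambda_theta = lambda_theta,
                 Rx = Rx, Rtheta = Rtheta, Px0 = Px0, Ptheta0 = Ptheta0,
                 x0_policy = x0_policy, x0 = x0, theta0 = theta0,
                 Gamma0 = Gamma0),
            class = "observer_config")
}

.check_spd <- function(M, nm) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(nm, " must be a square matrix", call. = FALSE)
  if (max(abs(M - t(M))) > 1e-8 * (1 + max(abs(M))))
    stop(nm, " must be symmetric", call. = FALSE)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(nm, " must be positive definite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  invisible(TRUE)
}

.expand_mat <- function(m, d, nm) {
  if (is.matrix(m)) {
    if (nrow(m) != d)
      stop(nm, " has dimension ", nrow(m), ", expected ", d, call. = FALSE)
    m
  } else diag(m, d)
}

#' @export
print.observer_config <- function(x, ...) {
  sc <- function(m) if (is.matrix(m)) paste0("<", nrow(m), "x", ncol(m),
                                             " matrix>") else paste0(m, "*I")
  cat("<observer_config> lambda_x=", x$lambda_x,
      " lambda_theta=", x$lambda_theta,
      " Rx=", sc(x$Rx), " Rtheta=", sc(x$Rtheta),
      " Px0=", sc(x$Px0), " Ptheta0=", sc(x$Ptheta0),
      " x0=", x$x0_policy, "\n", sep = "")
  invisible(x)
}

#' Initialise the observer state
#'
#' @param cfg an [observer_config()].
#' @param n number of states.
#' @param r number of library parameters.
#' @param first_measurement measurement vector used when
#'   `x0_policy = "first_measurement"`.
#' @return an object of class `observer_state` holding `x_hat`,
#'   `theta_hat`, `Px`, `Ptheta`, `Gamma`, the step counter `k`, and a
#'   `scratch` list filled by [compute_gains()].
#' @export
init_observer <- function(cfg, n, r, first_measurement = NULL) {
  stopifnot(inherits(cfg, "observer_config"), n >= 1, r >= 1)
  x_hat <- switch(cfg$x0_policy,
    zeros = numeric(n),
    explicit = {
      if (length(cfg$x0) != n) stop("x0 has wrong length", call. = FALSE)
      as.numeric(cfg$x0)
    },
    first_measurement = {
      if (is.null(first_measurement))
        stop("x0_policy 'first_measurement' needs first_measurement",
             call. = FALSE)
      if (length(first_measurement) != n)
        stop("first_measurement has wrong length", call. = FALSE)
      as.numeric(first_measurement)
    })
  theta_hat <- if (is.null(cfg$theta0)) numeric(r) else {
    if (length(cfg$theta0) != r) stop("theta0 has wrong length", call. = FALSE)
    as.numeric(cfg$theta0)
  }
  Gamma <- if (is.null(cfg$Gamma0)) matrix(0, n, r) else {
    if (!all(dim(cfg$Gamma0) == c(n, r)))
      stop("Gamma0 has wrong dimensions", call. = FALSE)
    cfg$Gamma0
  }
  structure(list(x_hat = x_hat, theta_hat = theta_hat,
                 Px = .expand_mat(cfg$Px0, n, "Px0"),
                 Ptheta = .expand_mat(cfg$Ptheta0, r, "Ptheta0"),
                 Gamma = Gamma, k = 0L, n = n, r = r,
                 Rx = .expand_mat(cfg$Rx, n, "Rx"),
                 Rtheta = .expand_mat(cfg$Rtheta, n, "Rtheta"),
                 scratch = NULL),
            class = "observer_state")
}

#' @export
print.observer_state <- function(x, ...) {
  cat("<observer_state> n=", x$n, " r=", x$r, " k=", x$k,
      "  |theta|=", format(sqrt(sum(x$theta_hat^2)), digits = 4), "\n", sep = "")
  invisible(x)
}

# gain core shared by compute_gains and the batch pipeline.
# Linear systems are solved (never explicitly inverted); both right-hand
# solves exploit symmetry of (Px + Rx) and Omega.
.gains <- function(Px, Ptheta, Gamma, Rx, Rtheta) {
  A <- Px + Rx
  Kx <- t(solve(A, Px))                      # Px (Px + Rx)^-1
  GP <- Gamma %*% Ptheta                     # n x r
  Omega <- GP %*% t(Gamma) + Rtheta          # n x n
  Ktheta <- t(solve(Omega, GP))              # Ptheta Gamma' Omega^-1, r x n
  list(Kx = Kx, Omega = Omega, Ktheta = Ktheta,
       Gamma_post = Gamma - Kx %*% Gamma)    # (I - Kx) Gamma
}

#' Compute the observer gains for the current step
#'
#' From the prior quantities of step k computes the state gain
#' \eqn{K_x = P_x (P_x + R_x)^{-1}}, the innovation matrix
#' \eqn{\Omega = \Gamma P_\theta \Gamma^\top + R_\theta}, the parameter
#' gain \eqn{K_\theta = P_\theta \Gamma^\top \Omega^{-1}}, and the
#' posterior sensitivity \eqn{\Gamma^+ = (I - K_x)\Gamma}. The results
#' are returned and also stored in `state$scratch` together with the
#' pre-update `Gamma_prior` needed by the prediction step.
#'
#' @param state an `observer_state` holding prior quantities.
#' @param cfg the matching `observer_config` (tuning matrices were frozen
#'   into the state at initialisation; cfg is accepted for interface
#'   symmetry and future time-varying tunings).
#' @return the updated `observer_state` (gains in `$scratch`).
#' @export
compute_gains <- function(state, cfg = NULL) {
  stopifnot(inherits(state, "observer_state"))
  g <- tryCatch(
    .gains(state$Px, state$Ptheta, state$Gamma, state$Rx, state$Rtheta),
    error = function(e)
      stop("gain computation failed (ill-conditioned Px + Rx or Omega): ",
           conditionMessage(e), call. = FALSE))
  state$scratch <- c(g, list(Gamma_prior = state$Gamma))
  state
}

#' Measurement update
#'
#' Applies the innovation \eqn{e = y - \bar x(k|k-1)}:
#' \eqn{\bar x(k|k) = \bar x(k|k-1) + (K_x + \Gamma^+ K_\theta) e} and
#' \eqn{\bar\theta(k|k) = \bar\theta(k|k-1) - K_\theta e} (the minus sign
#' in the parameter update is intrinsic to the recursion: the sensitivity
#' matrix accumulates \eqn{-\Psi}, so the two signs cancel), then sets
#' \eqn{\Gamma \leftarrow \Gamma^+}.
#'
#' @param state an `observer_state` with gains in `$scratch`
#'   (see [compute_gains()]).
#' @param y measurement vector.
#' @param cfg optional `observer_config` (unused; interface symmetry).
#' @return the updated `observer_state`.
#' @export
measurement_update <- function(state, y, cfg = NULL) {
  stopifnot(inherits(state, "observer_state"))
  if (is.null(state$scratch))
    stop("compute_gains must run before measurement_update", call. = FALSE)
  if (length(y) != state$n)
    stop("measurement has length ", length(y), ", expected ", state$n,
         call. = FALSE)
  s <- state$scratch
  e <- as.numeric(y) - state$x_hat
  state$x_hat <- state$x_hat +
    as.numeric((s$Kx + s$Gamma_post %*% s$Ktheta) %*% e)
  state$theta_hat <- state$theta_hat - as.numeric(s$Ktheta %*% e)
  state$Gamma <- s$Gamma_post
  state$scratch$innovation <- e
  state
}

#' Prediction update with exponential forgetting
#'
#' Propagates the estimates one step ahead:
#' \eqn{\bar x(k+1|k) = \bar x(k|k) + \Psi \bar\theta(k|k)},
#' \eqn{P_x \leftarrow \lambda_x^{-1} (I - K_x) P_x},
#' \eqn{P_\theta \leftarrow \lambda_\theta^{-1} (I - K_\theta
#' \Gamma_{prior}) P_\theta} (with \eqn{\Gamma_{prior}} the pre-update
#' sensitivity retained by [compute_gains()]), and
#' \eqn{\Gamma \leftarrow \Gamma(k|k) - \Psi}. Both covariance-like
#' matrices are re-symmetrised after the update; the one-sided forms are
#' symmetric only at infinite precision.
#'
#' @param state an `observer_state` after [measurement_update()].
#' @param Psi the n x r regressor matrix evaluated at the current sample.
#' @param cfg the `observer_config` providing the forgetting factors.
#' @return the updated `observer_state` with `k` advanced.
#' @export
prediction_update <- function(state, Psi, cfg) {
  stopifnot(inherits(state, "observer_state"),
            inherits(cfg, "observer_config"))
  if (!all(dim(Psi) == c(state$n, state$r)))
    stop("Psi has dimensions ", paste(dim(Psi), collapse = "x"),
         ", expected ", state$n, "x", state$r, call. = FALSE)
  s <- state$scratch
  if (is.null(s))
    stop("compute_gains must run before prediction_update", call. = FALSE)
  state$x_hat <- state$x_hat + as.numeric(Psi %*% state$theta_hat)
  Px <- (state$Px - s$Kx %*% state$Px) / cfg$lambda_x
  state$Px <- (Px + t(Px)) / 2
  Pt <- (state$Ptheta - s$Ktheta %*% (s$Gamma_prior %*% state$Ptheta)) /
    cfg$lambda_theta
  state$Ptheta <- (Pt + t(Pt)) / 2
  state$Gamma <- state$Gamma - Psi
  state$k <- state$k + 1L
  state
}

#' One full observer step
#'
#' Executes, in order: gain computation, measurement update with `y`,
#' regressor evaluation \eqn{\Psi(y, u)} on the *measurement* (not the
#' state estimate), and the prediction update.
#'
#' @param state an initialised `observer_state`.
#' @param y measurement vector at this sample.
#' @param u input vector at this sample (empty for autonomous systems).
#' @param lib the `odisco_library` defining \eqn{\Psi}.
#' @param cfg the `observer_config`.
#' @return the advanced `observer_state`.
#' @export
observer_step <- function(state, y, u = numeric(), lib, cfg) {
  state <- compute_gains(state, cfg)
  state <- measurement_update(state, y, cfg)
  Psi <- build_psi(lib, y, u)
  prediction_update(state, Psi, cfg)
}
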