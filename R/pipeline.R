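#' Run a full discovery pass over a time series
#'
#' Streams every sample through the adaptive observer in order and
#' records the posterior state and parameter estimates. The regressor is
#' evaluated on the measurements, so the whole pass is deterministic
#' given its inputs.
#'
#' @param ts a [time_series()].
#' @param lib an `odisco_library` matching the series dimensions.
#' @param cfg an [observer_config()].
#' @param keep_internals record per-step gains and sensitivities
#'   (needed by [theorem_residuals()]; costs memory).
#' @param log_every if positive, emit a progress message every so many
#'   samples.
#' @return an object of class `estimate_trajectory`: `theta_path` (N x r,
#'   posterior parameter estimates), `x_path` (N x n, posterior state
#'   estimates), `innovations` (N x n), the final `state`, `lib`, `cfg`,
#'   `dt`, and optionally `internals`.
#' @export
run_discovery <- function(ts, lib, cfg = observer_config(),
                          keep_internals = FALSE, log_every = 0) {
  stopifnot(inherits(ts, "time_series"), inherits(lib, "odisco_library"),
            inherits(cfg, "observer_config"))
  if (ncol(ts$Y) != lib$n_states)
    stop("series has ", ncol(ts$Y), " states but library expects ",
         lib$n_states, call. = FALSE)
  p <- if (is.null(ts$U)) 0 else ncol(ts$U)
  if (p != lib$n_inputs)
    stop("series has ", p, " inputs but library expects ", lib$n_inputs,
         call. = FALSE)
  N <- nrow(ts$Y); n <- lib$n_states; r <- lib$r
  V <- .term_values(lib, ts$Y, ts$U)   # N x r, batch term evaluation
  pos <- cbind(lib$row, seq_len(r))    # fixed nonzero positions of Psi

  st <- init_observer(cfg, n, r, first_measurement = ts$Y[1, ])
  x <- st$x_hat; th <- st$theta_hat
  Px <- st$Px; Pt <- st$Ptheta; G <- st$Gamma
  Rx <- st$Rx; Rt <- st$Rtheta
  lx <- cfg$lambda_x; lt <- cfg$lambda_theta
  Psi <- matrix(0, n, r)

  theta_path <- matrix(0, N, r)
  x_path <- matrix(0, N, n)
  innovations <- matrix(0, N, n)
  internals <- if (keep_internals)
    list(Kx = vector("list", N), Ktheta = vector("list", N),
         Gamma_post = vector("list", N), Gamma_pred = vector("list", N))
  else NULL

  for (k in seq_len(N)) {
    g <- .gains(Px, Pt, G, Rx, Rt)
    e <- ts$Y[k, ] - x
    x_post <- x + as.numeric((g$Kx + g$Gamma_post %*% g$Ktheta) %*% e)
    th <- th - as.numeric(g$Ktheta %*% e)
    if (any(!is.finite(th)) || any(!is.finite(x_post)))
      stop("estimate became non-finite at sample ", k, call. = FALSE)
    theta_path[k, ] <- th
    x_path[k, ] <- x_post
    innovations[k, ] <- e
    # prediction with exponential forgetting
    Psi[pos] <- V[k, ]
    x <- x_post + as.numeric(Psi %*% th)
    PxN <- (Px - g$Kx %*% Px) / lx
    Px <- (PxN + t(PxN)) / 2
    PtN <- (Pt - g$Ktheta %*% (G %*% Pt)) / lt
    Pt <- (PtN + t(PtN)) / 2
    G_post <- g$Gamma_post
    G <- G_post - Psi
    if (keep_internals) {
      internals$Kx[[k]] <- g$Kx
      internals$Ktheta[[k]] <- g$Ktheta
      internals$Gamma_post[[k]] <- G_post
      internals$Gamma_pred[[k]] <- G
    }
    if (log_every > 0 && k %% log_every == 0)
      message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " sample ", k, "/", N,
              " |theta| = ", format(sqrt(sum(th^2)), digits = 4))
  }
  st$x_hat <- x; st$theta_hat <- th
  st$Px <- Px; st$Ptheta <- Pt; st$Gamma <- G; st$k <- N
  structure(list(theta_path = theta_path, x_path = x_path,
                 innovations = innovations, state = st, lib = lib,
                 cfg = cfg, dt = ts$dt, t = ts$t, internals = internals),
            class = "estimate_trajectory")
}

#' @export
print.estimate_trajectory <- function(x, ...) {
  N <- nrow(x$theta_path)
  cat("<estimate_trajectory> N=", N, " r=", ncol(x$theta_path),
      " states=", ncol(x$x_path), "\n  final |theta| = ",
      format(sqrt(sum(x$theta_path[N, ]^2)), digits = 5), "\n", sep = "")
  invisible(x)
}

#' Converged parameter estimate of a discovery run
#'
#' Reads the converged value off the estimate trajectory as the mean of
#' the posterior parameter path over its final stretch, the numerical
#' analogue of reading the plateau of a convergence plot. Averaging over
#' the plateau suppresses the noise-driven jitter that a single final
#' sample retains under exponential forgetting.
#'
#' @param traj an `estimate_trajectory` (or an N x r matrix).
#' @param fraction fraction of the run to average over, from the end
#'   (default 0.2).
#' @return numeric vector of length r (discrete scale).
#' @export
converged_estimate <- function(traj, fraction = 0.2) {
  TH <- if (inherits(traj, "estimate_trajectory")) traj$theta_path else
    as.matrix(traj)
  stopifnot(fraction > 0, fraction <= 1)
  N <- nrow(TH)
  from <- max(1L, N - ceiling(fraction * N) + 1L)
  colMeans(TH[from:N, , drop = FALSE])
}

#' Reconstruct the continuous-time model
#'
#' Converts a discrete-scale parameter estimate into continuous-time
#' coefficients: entries with `|theta| < threshold` (absolute, discrete
#' scale) are zeroed, survivors are divided by `dt` (the Euler bridge),
#' and term labels are attached per state equation.
#'
#' @param theta_hat parameter vector (e.g. the last row of a
#'   `theta_path`), discrete scale.
#' @param lib the `odisco_library` the estimate refers to.
#' @param dt sampling interval (s).
#' @param threshold sparsity threshold on the discrete-scale magnitude;
#'   the default 5e-4 is half the resolution of a coefficient table
#'   printed to three decimals at dt = 1 ms.
#' @return an object of class `discovered_model` with `equations` (one
#'   data.frame of `label`, `coefficient` per state), the `dense` table
#'   of all continuous coefficients before thresholding, `dt`,
#'   `threshold`.
#' @export
reconstruct_model <- function(theta_hat, lib, dt, threshold = 5e-4) {
  stopifnot(inherits(lib, "odisco_library"), dt > 0, threshold >= 0)
  if (length(theta_hat) != lib$r)
    stop("theta_hat must have length r = ", lib$r, call. = FALSE)
  dense <- data.frame(index = seq_len(lib$r), state = lib$row,
                      label = lib$labels,
                      discrete = as.numeric(theta_hat),
                      coefficient = as.numeric(theta_hat) / dt)
  keep <- abs(dense$discrete) >= threshold
  equations <- lapply(seq_len(lib$n_states), function(j) {
    sel <- keep & dense$state == j
    data.frame(label = dense$label[sel], coefficient = dense$coefficient[sel])
  })
  structure(list(equations = equations, dense = dense, dt = dt,
                 threshold = threshold, n_states = lib$n_states),
            class = "discovered_model")
}

#' @export
print.discovered_model <- function(x, ...) {
  cat("<discovered_model> dt=", x$dt, "s threshold=", x$threshold,
      " (discrete scale)\n", sep = "")
  for (j in seq_len(x$n_states)) {
    eq <- x$equations[[j]]
    rhs <- if (nrow(eq) == 0) "0" else
      paste(sprintf("%+.4g*%s", eq$coefficient, eq$label), collapse = " ")
    cat("  dx", j, "/dt = ", rhs, "\n", sep = "")
  }
  invisible(x)
}

#' Coefficient matrix of a discovered model
#'
#' @param model a `discovered_model`.
#' @return the dense data.frame of continuous coefficients.
#' @export
model_coefficients <- function(model) {
  stopifnot(inherits(model, "discovered_model"))
  model$dense
}

#' Persistent-excitation diagnostic
#'
#' Accumulates the windowed regressor Gramian
#' \eqn{\sum_{l=k-\xi}^{k} \Psi(l)^\top \Psi(l)} for every admissible k
#' and records its minimum eigenvalue. The sequence is persistently
#' exciting when the smallest of these minima stays above a tolerance.
#'
#' @param ts a [time_series()].
#' @param lib an `odisco_library`.
#' @param window_xi window length \eqn{\xi} (samples); each Gramian sums
#'   `window_xi + 1` terms.
#' @param tol positive-definiteness tolerance; the default scales with
#'   the window length to separate rank deficiency from roundoff.
#' @return an object of class `excitation_report`: `min_eigenvalues`
#'   (one per window end), `kappa_hat` (global minimum, clamped at 0),
#'   `window_xi`, `tol`, `persistent`.
#' @export
excitation_gramian <- function(ts, lib, window_xi,
                               tol = 1e-8 * (window_xi + 1)) {
  stopifnot(inherits(ts, "time_series"), inherits(lib, "odisco_library"))
  N <- nrow(ts$Y)
  if (window_xi < 0 || window_xi >= N)
    stop("window_xi must lie in [0, N)", call. = FALSE)
  V <- .term_values(lib, ts$Y, ts$U)
  # Psi(l)' Psi(l) has entry (i, j) = V[l, i] V[l, j] when terms i and j
  # share a state row, 0 otherwise: a masked cross product.
  mask <- outer(lib$row, lib$row, "==") * 1
  ends <- (window_xi + 1):N
  mins <- numeric(length(ends))
  Gr <- crossprod(V[1:(window_xi + 1), , drop = FALSE]) * mask
  for (m in seq_along(ends)) {
    k <- ends[m]
    if (m > 1) {
      vin <- V[k, ]; vout <- V[k - window_xi - 1, ]
      Gr <- Gr + (tcrossprod(vin) - tcrossprod(vout)) * mask
    }
    mins[m] <- min(eigen(Gr, symmetric = TRUE, only.values = TRUE)$values)
  }
  kappa <- max(0, min(mins))
  structure(list(min_eigenvalues = mins, k = ends, kappa_hat = kappa,
                 window_xi = window_xi, tol = tol,
                 persistent = kappa > tol),
            class = "excitation_report")
}

#' @export
print.excitation_report <- function(x, ...) {
  cat("<excitation_report> window xi=", x$window_xi,
      " kappa_hat=", format(x$kappa_hat, digits = 4),
      " tol=", format(x$tol, digits = 3), " -> ",
      if (x$persistent) "persistent" else "NOT persistent", "\n", sep = "")
  invisible(x)
}

#' Accuracy of a parameter-estimate trajectory against known truth
#'
#' The per-step accuracy is `1 - ||theta_hat_active(k) - theta_active|| /
#' ||theta_active||` (Euclidean norm over the active entries), so it is
#' 1 exactly at the truth and 0 for the all-zero initial estimate. The
#' per-parameter mode instead reports the worst single-entry relative
#' accuracy.
#'
#' @param traj an `estimate_trajectory` (or an N x r matrix of
#'   estimates).
#' @param theta_true true parameter vector, length r.
#' @param active_set indices of active (identifiable) parameters;
#'   defaults to the nonzero entries of `theta_true`.
#' @param mode `"vector"` (norm-based, default) or `"per_parameter"`.
#' @return an object of class `accuracy_trace`: `accuracy` (length N),
#'   `theta_true`, `active_set`, `final_rel_error` (per active entry),
#'   `eps_theta_final`.
#' @export
accuracy_trace <- function(traj, theta_true, active_set = NULL,
                           mode = c("vector", "per_parameter")) {
  mode <- match.arg(mode)
  TH <- if (inherits(traj, "estimate_trajectory")) traj$theta_path else
    as.matrix(traj)
  if (ncol(TH) != length(theta_true))
    stop("theta_true length does not match trajectory", call. = FALSE)
  if (is.null(active_set)) active_set <- which(theta_true != 0)
  if (length(active_set) == 0)
    stop("active_set is empty", call. = FALSE)
  ta <- theta_true[active_set]
  denom <- sqrt(sum(ta^2))
  if (denom == 0) stop("||theta_active|| is zero", call. = FALSE)
  E <- TH[, active_set, drop = FALSE] -
    matrix(ta, nrow(TH), length(ta), byrow = TRUE)
  acc <- if (mode == "vector") {
    unname(1 - sqrt(rowSums(E^2)) / denom)
  } else {
    1 - apply(abs(E) / matrix(abs(ta), nrow(TH), length(ta), byrow = TRUE),
              1, max)
  }
  N <- nrow(TH)
  structure(list(accuracy = acc, theta_true = theta_true,
                 active_set = active_set, mode = mode,
                 final_rel_error = abs(E[N, ]) / abs(ta),
                 eps_theta_final = TH[N, ] - theta_true),
            class = "accuracy_trace")
}

#' Sustained-crossing convergence sample
#'
#' Number of observations consumed before the accuracy trace rises above
#' `level` and stays there for the remainder of the run (the sustained
#' crossing): 0 when the trace is above the level throughout, `NA` when
#' the crossing is never sustained.
#'
#' @param trace an `accuracy_trace` or a numeric accuracy vector.
#' @param level accuracy level in (0, 1), e.g. 0.8.
#' @return integer sample count, or `NA_integer_`.
#' @export
convergence_sample <- function(trace, level = 0.8) {
  if (inherits(trace, "accuracy_trace")) trace <- trace$accuracy
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)", call. = FALSE)
  ok <- trace >= level
  if (!ok[length(ok)]) return(NA_integer_)
  # last failure index; everything after it is sustained
  last_bad <- max(c(0L, which(!ok)))
  as.integer(last_bad)
}

#' Error-recursion residuals of the convergence identities
#'
#' On noise-free data generated exactly by the discrete approximation
#' model (see [euler_fixture()]) the observer's errors obey three exact
#' recursions: the sensitivity propagation
#' \eqn{\Gamma(k+1|k+1) = (I - K_x(k+1))(\Gamma(k|k) - \Psi(k))}, the
#' combined-error contraction
#' \eqn{\epsilon(k+1) = (I - K_x(k+1))\epsilon(k)} with
#' \eqn{\epsilon = \epsilon_x + \Gamma\epsilon_\theta}, and the
#' parameter-error recursion
#' \eqn{\epsilon_\theta(k+1) = (I - K_\theta(k+1)\Gamma(k+1|k))
#' \epsilon_\theta(k) + K_\theta(k+1)\epsilon(k)}. This function runs the
#' observer over the fixture and reports the per-step residual norms of
#' all three, which should sit at numerical-noise level.
#'
#' @param traj an `estimate_trajectory` with internals, or `NULL` to run
#'   the observer here.
#' @param ts the noise-free fixture [time_series()] (measurements equal
#'   states).
#' @param theta_true the generating parameter vector.
#' @param lib the `odisco_library`.
#' @param cfg the [observer_config()].
#' @return a data.frame with columns `k`, `res_gamma` (relative to the
#'   sensitivity magnitude), `res_combined`, `res_theta`, `eps_norm`
#'   (one row per transition k -> k+1).
#' @export
theorem_residuals <- function(traj = NULL, ts, theta_true, lib,
                              cfg = observer_config()) {
  if (length(theta_true) != lib$r)
    stop("theta_true must have length r = ", lib$r, call. = FALSE)
  if (is.null(traj) || is.null(traj$internals))
    traj <- run_discovery(ts, lib, cfg, keep_internals = TRUE)
  N <- nrow(traj$theta_path)
  V <- .term_values(lib, ts$Y, ts$U)
  pos <- cbind(lib$row, seq_len(lib$r))
  n <- lib$n_states
  In <- diag(n)
  eps_x <- traj$x_path - ts$Y            # posterior state error (y = x here)
  eps_th <- traj$theta_path -
    matrix(theta_true, N, lib$r, byrow = TRUE)
  res_gamma <- res_comb <- res_theta <- eps_norm <- numeric(N - 1)
  Psi <- matrix(0, n, lib$r)
  for (k in seq_len(N - 1)) {
    Kx1 <- traj$internals$Kx[[k + 1]]
    Kt1 <- traj$internals$Ktheta[[k + 1]]
    Gk <- traj$internals$Gamma_post[[k]]
    Gk1 <- traj$internals$Gamma_post[[k + 1]]
    Gpred <- traj$internals$Gamma_pred[[k]]
    Psi[pos] <- V[k, ]
    eps_k <- eps_x[k, ] + as.numeric(Gk %*% eps_th[k, ])
    eps_k1 <- eps_x[k + 1, ] + as.numeric(Gk1 %*% eps_th[k + 1, ])
    res_gamma[k] <- max(abs(Gk1 - (In - Kx1) %*% (Gk - Psi))) /
      (1 + max(abs(Gk1)))
    res_comb[k] <- sqrt(sum((eps_k1 - as.numeric((In - Kx1) %*% eps_k))^2))
    pred <- eps_th[k, ] - as.numeric(Kt1 %*% (Gpred %*% eps_th[k, ])) +
      as.numeric(Kt1 %*% eps_k)
    res_theta[k] <- sqrt(sum((eps_th[k + 1, ] - pred)^2))
    eps_norm[k] <- sqrt(sum(eps_k^2))
  }
  data.frame(k = seq_len(N - 1), res_gamma = res_gamma,
             res_combined = res_comb, res_theta = res_theta,
             eps_norm = eps_norm)
}
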