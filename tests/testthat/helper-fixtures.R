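# shared fixtures and independent oracles for the test suite

# dense reference transcription of the observer recursion, written
# straight from the update equations with explicit matrix inverses.
# Deliberately naive: it is the oracle the fast implementation is
# checked against, not a second copy of it.
ref_observer_step <- function(x, th, Px, Pt, G, y, Psi, Rx, Rt, lx, lt) {
  n <- length(x)
  Kx <- Px %*% solve(Px + Rx)
  Omega <- G %*% Pt %*% t(G) + Rt
  Kt <- Pt %*% t(G) %*% solve(Omega)
  G_post <- (diag(n) - Kx) %*% G
  e <- y - x
  x_post <- x + as.numeric((Kx + G_post %*% Kt) %*% e)
  th_post <- th - as.numeric(Kt %*% e)
  x_pred <- x_post + as.numeric(Psi %*% th_post)
  Px_new <- (diag(n) - Kx) %*% Px / lx
  Pt_new <- (diag(nrow(Pt)) - Kt %*% G) %*% Pt / lt
  list(x = x_pred, th = th_post, Px = Px_new, Pt = Pt_new,
       G = G_post - Psi, Kx = Kx, Kt = Kt, Omega = Omega, G_post = G_post,
       x_post = x_post)
}

random_spd <- function(d) {
  A <- matrix(stats::rnorm(d * d), d)
  crossprod(A) + diag(d) * 0.1
}

# high-trust tuning for noise-free fixture data: tiny measurement
# penalties, wide initial parameter covariance
noisefree_config <- function() {
  observer_config(lambda_x = 0.995, lambda_theta = 0.999,
                  Rx = 1e-9, Rtheta = 1e-6, Px0 = 0.1, Ptheta0 = 1e4)
}

# per-system exact-recovery fixture settings: the fixture step is chosen
# so that 10*r samples span the system's characteristic dynamics
recovery_cases <- function() {
  list(
    msd            = list(dt = 0.01, input = NULL, x0 = NULL),
    lorenz         = list(dt = 0.005, input = NULL, x0 = NULL),
    rossler        = list(dt = 0.05, input = NULL, x0 = rossler_x0()),
    lotka_volterra = list(dt = 0.05, input = NULL, x0 = NULL),
    van_der_pol    = list(dt = 0.05, input = NULL, x0 = NULL),
    linear_control = list(dt = 0.02, x0 = NULL,
                          input = make_input("sinusoid", amplitude = 10,
                                             frequency = 1)),
    maglev         = list(dt = 0.01, x0 = NULL,
                          input = make_input("sinusoid", amplitude = 2,
                                             frequency = 5, offset = 5)))
}

# on-attractor Roessler initial state (after a 200 s spin-up from (1,1,1))
rossler_x0 <- function() c(-15.014, -6.717, 0.003)
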