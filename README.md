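# odisco — online discovery of governing equations from time series

`odisco` recovers the governing ordinary differential equations of a
dynamical system from noisy, uniformly sampled measurements — online,
one sample at a time, without batch optimisation or training. It is
aimed at researchers in systems biology, ecology and engineering who
have sensor streams from a system whose model structure is unknown or
only partially known, and who want an interpretable sparse ODE rather
than a black-box predictor.

## Method

For a system x&#775;(t) = f(x, u, θ) observed through y(k) = x(k) + v(k),
v ~ N(0, R), the one-step Euler bridge
x(k+1) = x(k) + Δt·f(x(k), u(k), θ) is approximated by the
linear-in-parameters surrogate

    x(k+1) = x(k) + Ψ(y(k), u(k)) θ,

where Ψ ∈ ℝ^(n×r) stacks a wide library of candidate basis functions
(constants, monomials and cross products, sin/cos, rational and custom
terms) and θ holds one coefficient per placed term. A recursive adaptive
observer estimates the state x̄ and coefficients θ̄ jointly: each sample
updates gains Kx = Px(Px+Rx)⁻¹ and Kθ = PθΓᵀ(ΓPθΓᵀ+Rθ)⁻¹, applies the
innovation, and propagates with exponential forgetting factors λx, λθ
while the sensitivity matrix Γ accumulates −Ψ. Under persistent
excitation — the windowed Gramian Σ Ψ(l)ᵀΨ(l) uniformly positive
definite — the estimation errors decay exponentially. Dividing the
converged θ̄ by Δt and thresholding small entries yields the
continuous-time model.

The package bundles simulators for seven benchmark systems
(mass-spring-damper, Lorenz, Roessler, Lotka-Volterra, Van der Pol, a
driven linear control system, magnetic levitation), exact discrete-time
fixture generators for the invariant suites, a persistent-excitation
diagnostic, accuracy/convergence scoring against known truth, lossless
CSV time-series I/O, YAML run configs, and a small CLI
(`inst/cli/odisco`) with `simulate`, `discover`, `check-excitation` and
`eval` subcommands.

## Worked example

Discover the mass-spring-damper dynamics (m = 1 kg, k = 84 N/m,
b = 0.9 Ns/m) from 5 s of 1 kHz measurements corrupted by sd-1 Gaussian
noise:

```r
library(odisco)

lib <- benchmark_library("msd")            # y1, y2, y1^2, y2^2, y1*y2 per equation
sys <- benchmark_system("msd")
ts  <- simulate_system(sys, dt = 0.001, n_steps = 5000)
ts  <- add_measurement_noise(ts, noise_spec(1, seed = 1))

tr    <- run_discovery(ts, lib)            # benchmark observer tuning
model <- reconstruct_model(converged_estimate(tr), lib, dt = ts$dt)
model
#> <discovered_model> dt=0.001s threshold=5e-04 (discrete scale)
#>   dx1/dt = +0.9999*y2
#>   dx2/dt = -83.64*y1 -0.9334*y2

acc <- accuracy_trace(tr, true_parameters("msd", lib, ts$dt))
convergence_sample(acc, 0.8)
#> [1] 262

excitation_gramian(ts, lib, window_xi = 200)
#> <excitation_report> window xi=200 kappa_hat=6.663 tol=2.01e-06 -> persistent
```

Reading the output: the recovered model is ẋ = v, v̇ = −83.6x − 0.93v —
a spring constant of 83.6 N/m and damping of 0.93 Ns/m against the true
84 and 0.9 (the small offsets are the Euler-bridge and noisy-regressor
bias). All six nonlinear candidate terms were thresholded to zero. The
estimate sustains 80% accuracy after 262 observations, and the windowed
regressor Gramian confirms the free decay is persistently exciting.

The same flow from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","odisco",package="odisco"))')
Rscript $CLI simulate --system msd --dt 0.001 --steps 5000 --noise-sd 1 --seed 1 -o msd.csv
Rscript $CLI discover msd.csv --library msd -o model.json --trace trace.csv
Rscript $CLI check-excitation msd.csv --library msd --window 200
```

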