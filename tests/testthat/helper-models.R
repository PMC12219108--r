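# Shared fixtures built in code.

# brute-force double-loop evaluation of the standard Kuramoto RHS
loop_kuramoto_rhs <- function(phases, omega, coupling) {
  n <- length(phases)
  d <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) s <- s + sin(phases[j] - phases[i])
    d[i] <- omega[i] + coupling / n * s
  }
  d
}

# brute-force double-loop evaluation of the bi-harmonic RHS
loop_biharmonic_rhs <- function(phases, omega, coupling, g1, g2, a) {
  n <- length(phases)
  d <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      dphi <- phases[j] - phases[i]
      s <- s + sin(dphi + g1) + a * sin(2 * dphi + g2)
    }
    d[i] <- omega[i] + coupling / n * s
  }
  d
}

# one RK4 step in R, for cross-checking compiled integrators
rk4_step_r <- function(f, y, dt) {
  k1 <- f(y)
  k2 <- f(y + dt / 2 * k1)
  k3 <- f(y + dt / 2 * k2)
  k4 <- f(y + dt * k3)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# small trained standard reservoir on a synchronous Kuramoto trajectory,
# reused by reservoir- and evaluation-level tests
make_small_setup <- function(seed = 5, n_train = 300, size = 80) {
  params <- sample_regime("parameter_error", "synchrony", seed = seed)
  set.seed(seed + 1)
  init <- runif(params$n_oscillators, -pi, pi)
  traj <- integrate_oscillators(params, init, 0.1, n_train + 200)
  u <- phases_to_components(traj$phases)
  spec <- reservoir_spec(size = size, seed = seed)
  A <- build_internal(spec)
  B <- build_input(spec, ncol(u))
  list(params = params, u = u, spec = spec, A = A, B = B,
       inputs = u[1:n_train, ], targets = u[2:(n_train + 1), ])
}
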