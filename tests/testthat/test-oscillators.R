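test_that("regime sampling matches the published parameter tables", {
  p <- sample_regime("parameter_error", "synchrony", seed = 3)
  expect_s3_class(p, "kuramoto_params")
  expect_identical(p$n_oscillators, 5L)
  expect_equal(p$coupling, 4.0)
  expect_true(all(abs(p$natural_frequencies) <= 1))

  expect_equal(sample_regime("parameter_error", "asynchrony", 3)$coupling, 1.0)

  h <- sample_regime("residual_physics", "heteroclinic_cycles", seed = 3)
  expect_s3_class(h, "biharmonic_params")
  expect_identical(h$n_oscillators, 10L)
  expect_equal(h$coupling, 1.0)
  expect_equal(h$gamma1, 1.3)
  expect_equal(h$gamma2, pi)
  expect_equal(h$second_harmonic_scale, 0.2)
  expect_equal(h$freq_width, 0.01)

  s <- sample_regime("residual_physics", "synchrony", 3)
  expect_equal(s$gamma1, 2 * pi)
  expect_equal(sample_regime("residual_physics", "asynchrony", 3)$coupling, 5.0)
  expect_equal(sample_regime("residual_physics", "partial_synchrony", 3)$gamma1, 1.5)

  expect_error(sample_regime("parameter_error", "heteroclinic_cycles", 1),
               "valid regimes")
  # bit-reproducible given the seed
  expect_identical(sample_regime("residual_physics", "synchrony", 11),
                   sample_regime("residual_physics", "synchrony", 11))
})

test_that("multi-frequency regime puts the fast oscillator at z(3 + w)", {
  p <- sample_regime("parameter_error", "multi_frequency", seed = 9)
  expect_equal(p$coupling, 2.0)
  expect_true(all(abs(p$natural_frequencies[1:4]) <= 1))
  expect_true(abs(p$natural_frequencies[5]) >= 3 &&
                abs(p$natural_frequencies[5]) <= 4)
  # boundary of the construction: w = 0, z = +1 gives exactly 3
  q <- p
  q$natural_frequencies[5] <- 1 * (3.0 + 0)
  expect_equal(q$natural_frequencies[5], 3.0)
})

test_that("kuramoto_rhs matches a double-loop oracle and its limits", {
  p <- kuramoto_params(5, c(-0.3, 0.1, 0.7, -0.9, 0.2), 1.7)
  set.seed(1)
  th <- runif(5, -pi, pi)
  expect_equal(kuramoto_rhs(th, p),
               loop_kuramoto_rhs(th, p$natural_frequencies, p$coupling),
               tolerance = 1e-12)
  # equal phases: the coupling sum vanishes
  expect_equal(kuramoto_rhs(rep(0.4, 5), p), p$natural_frequencies)
  # antisymmetric sine pair
  p2 <- kuramoto_params(2, c(0, 0), 2)
  expect_equal(kuramoto_rhs(c(0, pi / 2), p2), c(1, -1))
  expect_error(kuramoto_rhs(c(0, 0), p), "length 5")
})

test_that("biharmonic_rhs matches its oracle and reduces to the first harmonic", {
  p <- biharmonic_params(3, c(0.01, -0.02, 0.005), 1.0, gamma1 = 1.3,
                         gamma2 = pi, second_harmonic_scale = 0.2)
  set.seed(2)
  th <- runif(3, -pi, pi)
  expect_equal(biharmonic_rhs(th, p),
               loop_biharmonic_rhs(th, p$natural_frequencies, p$coupling,
                                   1.3, pi, 0.2),
               tolerance = 1e-12)
  # a = 0, gamma1 = 0 reduces exactly to the standard model
  p0 <- biharmonic_params(3, p$natural_frequencies, p$coupling, gamma1 = 0,
                          gamma2 = pi, second_harmonic_scale = 0)
  kp <- as_kuramoto(p)
  set.seed(3)
  for (rep in 1:5) {
    th <- runif(3, -pi, pi)
    expect_equal(biharmonic_rhs(th, p0), kuramoto_rhs(th, kp),
                 tolerance = 1e-12)
  }
  # gamma1 = 2*pi is the same as gamma1 = 0 (synchrony-row convention)
  p2pi <- biharmonic_params(3, p$natural_frequencies, p$coupling,
                            gamma1 = 2 * pi, gamma2 = pi,
                            second_harmonic_scale = 0.2)
  pz <- biharmonic_params(3, p$natural_frequencies, p$coupling, gamma1 = 0,
                          gamma2 = pi, second_harmonic_scale = 0.2)
  expect_equal(biharmonic_rhs(th, p2pi), biharmonic_rhs(th, pz),
               tolerance = 1e-12)
})

test_that("component RHS agrees with the chain rule applied to the phase RHS", {
  p <- kuramoto_params(4, c(0.5, -0.2, 0.9, 0.05), 2.3)
  set.seed(4)
  for (rep in 1:10) {
    th <- runif(4, -pi, pi)
    u <- phases_to_components(th)
    dth <- kuramoto_rhs(th, p)
    # d/dt (cos th, sin th) = (-sin th * dth, cos th * dth)
    expected <- as.vector(rbind(-sin(th) * dth, cos(th) * dth))
    expect_equal(kuramoto_component_rhs(u, p), expected, tolerance = 1e-12)
  }
  # K = 0: pure rotation of each pair
  p0 <- kuramoto_params(4, p$natural_frequencies, 0)
  u <- phases_to_components(runif(4, -pi, pi))
  d <- kuramoto_component_rhs(u, p0)
  x <- u[c(1, 3, 5, 7)]; y <- u[c(2, 4, 6, 8)]
  expect_equal(d[c(1, 3, 5, 7)], -p$natural_frequencies * y)
  expect_equal(d[c(2, 4, 6, 8)], p$natural_frequencies * x)
})

test_that("phase/component transforms invert each other", {
  expect_equal(phases_to_components(0), c(1, 0))
  expect_equal(components_to_phases(c(1, 0)), 0)
  # independent trig evaluation at 2.5 rad
  u <- phases_to_components(2.5)
  expect_equal(u, c(cos(2.5), sin(2.5)), tolerance = 1e-15)
  expect_equal(u[1], -0.80114, tolerance = 1e-5)
  expect_equal(u[2], 0.59847, tolerance = 1e-5)
  expect_equal(components_to_phases(u), 2.5, tolerance = 1e-12)
  # round trip is the identity on [-pi, pi), matrices included
  set.seed(5)
  th <- matrix(runif(30, -pi, pi), 10, 3)
  expect_equal(components_to_phases(phases_to_components(th)), th,
               tolerance = 1e-12)
  expect_error(components_to_phases(c(0, 0)), "degenerate")
})

test_that("integration is exact in the uncoupled limit and wraps phases", {
  p <- kuramoto_params(3, c(0.7, -1.2, 2.0), 0)
  init <- c(0.1, -2.0, 3.0)
  tr <- integrate_oscillators(p, init, dt = 0.1, n_steps = 500)
  expect_equal(dim(tr$phases), c(501L, 3L))
  expect_equal(tr$phases[1, ], wrap_phase(init))
  tt <- 0.1 * (0:500)
  expected <- wrap_phase(outer(tt, p$natural_frequencies) +
                           rep(init, each = 501))
  expect_equal(tr$phases, expected, tolerance = 1e-9)
  expect_true(all(tr$phases >= -pi & tr$phases < pi))
})

test_that("two locked oscillators settle at the closed-form phase difference", {
  # dpsi/dt = dw - K sin(psi) (N = 2, psi = th1 - th2) -> psi* = asin(dw/K)
  dw <- 0.6; k <- 1.0
  p <- kuramoto_params(2, c(dw / 2, -dw / 2), k)
  tr <- integrate_oscillators(p, c(0.3, -0.8), dt = 0.01, n_steps = 6000)
  psi <- wrap_phase(tr$phases[, 1] - tr$phases[, 2])
  expect_equal(psi[length(psi)], asin(dw / k), tolerance = 1e-6)
})

test_that("integrated component magnitudes are exactly 1", {
  p <- sample_regime("residual_physics", "partial_synchrony", seed = 8)
  set.seed(8)
  tr <- integrate_oscillators(p, runif(10, -pi, pi), 0.1, 200)
  u <- as_component_trajectory(tr)$components
  n <- 10
  mags <- u[, 2 * seq_len(n) - 1]^2 + u[, 2 * seq_len(n)]^2
  expect_equal(max(abs(mags - 1)), 0, tolerance = 1e-9)
})

test_that("parameter perturbation applies multiplicative error of the right size", {
  p <- kuramoto_params(5, c(0.1, -0.4, 0.7, 0.2, -0.9), 4.0)
  expect_identical(perturb_params(p, 0, 0), p)
  set.seed(10)
  ratios <- replicate(10000, perturb_params(p, 0.05, 0)$coupling / p$coupling)
  expect_lt(abs(mean(ratios) - 1), 0.005)
  expect_lt(abs(sd(ratios) - 0.05), 0.005)
  # frequencies perturbed independently, harmonics untouched
  b <- sample_regime("residual_physics", "heteroclinic_cycles", 2)
  set.seed(11)
  b2 <- perturb_params(b, 0.05, 0.05)
  expect_identical(b2$gamma1, b$gamma1)
  expect_identical(b2$gamma2, b$gamma2)
  expect_identical(b2$second_harmonic_scale, b$second_harmonic_scale)
  expect_true(all(b2$natural_frequencies != b$natural_frequencies))
})

test_that("expert_step is one RK4 step of the component dynamics", {
  p <- kuramoto_params(3, c(0.4, -0.1, 0.8), 1.5)
  set.seed(12)
  th <- runif(3, -pi, pi)
  u <- phases_to_components(th)
  oracle <- rk4_step_r(function(v) kuramoto_component_rhs(v, p), u, 0.1)
  expect_equal(expert_step(p, u, 0.1), oracle, tolerance = 1e-12)
  # dt -> 0 returns the input
  expect_equal(expert_step(p, u, 0), u)
  # single uncoupled oscillator: one step of a pure rotation
  p1 <- kuramoto_params(1, 1, 0)
  expect_equal(expert_step(p1, c(1, 0), 0.1), c(cos(0.1), sin(0.1)),
               tolerance = 1e-7)
})

test_that("synchrony and asynchrony regimes separate in the order parameter", {
  # the locked order parameter depends on the frequency spread of the draw;
  # with K = 4 and omega in (-1, 1) it settles above ~0.97
  ps <- sample_regime("parameter_error", "synchrony", seed = 21)
  set.seed(21)
  trs <- integrate_oscillators(ps, runif(5, -pi, pi), 0.1, 3000)
  expect_gt(min(order_parameter(trs$phases[2000:3001, ])), 0.97)

  pa <- sample_regime("parameter_error", "asynchrony", seed = 21)
  set.seed(22)
  tra <- integrate_oscillators(pa, runif(5, -pi, pi), 0.1, 3000)
  expect_lt(mean(order_parameter(tra$phases[1000:3001, ])), 0.99)
})
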