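test_that("internal matrix hits the requested spectral radius across seeds", {
  for (s in 1:20) {
    spec <- reservoir_spec(size = 120, spectral_radius = 0.4, seed = s)
    a <- build_internal(spec)
    expect_lt(abs(spectral_radius(a) - 0.4), 1e-8)
  }
  # rho = 0 means the exact zero matrix (memoryless reservoir)
  a0 <- build_internal(reservoir_spec(size = 50, spectral_radius = 0, seed = 1))
  expect_equal(Matrix::nnzero(a0), 0)
  # baseline-sized build
  ab <- build_internal(reservoir_spec(seed = 3))
  expect_lt(abs(spectral_radius(ab) - 0.4), 1e-8)
  # reproducibility: same seed, bit-identical matrices
  expect_identical(build_internal(reservoir_spec(seed = 7)),
                   build_internal(reservoir_spec(seed = 7)))
})

test_that("internal matrix density matches the Erdos-Renyi mean degree", {
  d <- 200; deg <- 3
  counts <- vapply(1:50, function(s) {
    Matrix::nnzero(build_internal(reservoir_spec(size = d, mean_degree = deg,
                                                 seed = s)))
  }, numeric(1))
  # 99% normal interval for the mean of 50 Binomial(d^2, deg/d) counts
  expect_lt(abs(mean(counts) - d * deg), 2.58 * sqrt(d * deg) / sqrt(50))
})

test_that("input matrix has one uniform connection per node", {
  spec <- reservoir_spec(size = 10000, input_scaling = 0.15, seed = 2)
  b <- build_input(spec, 10)
  expect_true(all(rowSums(b != 0) == 1))
  expect_true(all(abs(b) <= 0.15))
  # column assignment is uniform (chi-square at alpha = 0.01)
  cols <- apply(b != 0, 1, which)
  expect_gt(chisq.test(table(factor(cols, levels = 1:10)))$p.value, 0.01)
  expect_identical(b, build_input(spec, 10))
})

test_that("the update rule is a leakless tanh map", {
  # scalar hand evaluation
  expect_equal(reservoir_update(matrix(0.5), matrix(1.0), 0.2, 0.3),
               tanh(0.4), tolerance = 1e-12)
  # zero weights give the zero state
  expect_equal(reservoir_update(matrix(0, 3, 3), matrix(0, 3, 2),
                                rep(1, 3), c(2, 2)), rep(0, 3))
  # activations stay strictly inside (-1, 1)
  st <- make_small_setup()
  r <- reservoir_update(st$A, st$B, rnorm(st$spec$size, sd = 10), st$u[1, ])
  expect_true(all(abs(r) < 1))
  expect_error(reservoir_update(st$A, st$B, rep(0, 3), st$u[1, ]),
               "dimension mismatch")
})

test_that("g squares even (1-based) positions only", {
  expect_equal(apply_g(c(1, 2, 3, 4)), c(1, 4, 3, 16))
  expect_equal(apply_g(rep(0, 6)), rep(0, 6))
  expect_equal(apply_g(c(-2, -2)), c(-2, 4))
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(apply_g(m), matrix(c(1, 4, 3, 16), 2, 2))
})

test_that("drive equals the step-by-step composition of updates", {
  st <- make_small_setup()
  inputs <- st$u[1:25, ]
  states <- drive(st$A, st$B, numeric(st$spec$size), inputs)
  expect_equal(dim(states), c(st$spec$size, 25L))
  r <- numeric(st$spec$size)
  for (t in 1:25) {
    r <- reservoir_update(st$A, st$B, r, inputs[t, ])
    expect_equal(states[, t], r, tolerance = 1e-15)
  }
})

test_that("reservoirs at baseline contract to the driven trajectory", {
  # echo-state smoke property: two different initial states driven by the
  # same 200-step input end up indistinguishable
  st <- make_small_setup(size = 150)
  inputs <- st$u[1:200, ]
  s1 <- drive(st$A, st$B, numeric(150), inputs)
  set.seed(99)
  s2 <- drive(st$A, st$B, runif(150, -1, 1), inputs)
  expect_lt(max(abs(s1[, 200] - s2[, 200])), 1e-6)
})

test_that("ridge training matches the normal-equations oracle", {
  set.seed(20)
  d <- 10; n <- 50
  rhat <- matrix(rnorm(d * n), d, n)
  targ <- matrix(rnorm(4 * n), 4, n)
  hist <- structure(list(transformed = rhat, targets = targ),
                    class = "state_history")
  for (beta in c(1e-6, 1e-2, 1)) {
    c_pkg <- train_readout(hist, beta)
    c_oracle <- targ %*% t(rhat) %*% solve(rhat %*% t(rhat) + beta * diag(d))
    expect_equal(c_pkg, c_oracle, tolerance = 1e-8)
  }
  # shrinkage: ||C|| non-increasing in beta, -> 0 as beta -> Inf
  norms <- vapply(c(1e-6, 1e-2, 1, 100, 1e6),
                  function(b) norm(train_readout(hist, b), "F"), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
  expect_lt(norms[5], 1e-3)
})

test_that("a planted readout is recovered from abundant data", {
  set.seed(21)
  d <- 10; n <- 400
  rhat <- matrix(rnorm(d * n), d, n)
  c0 <- matrix(rnorm(3 * d), 3, d)
  hist <- structure(list(transformed = rhat, targets = c0 %*% rhat),
                    class = "state_history")
  expect_equal(train_readout(hist, 1e-12), c0, tolerance = 1e-6)
})

test_that("rank-deficient systems without regularization are refused", {
  rhat <- matrix(1, 4, 30) # rank 1
  hist <- structure(list(transformed = rhat,
                         targets = matrix(rnorm(60), 2, 30)),
                    class = "state_history")
  expect_error(train_readout(hist, 0), "beta > 0")
})

test_that("normalization projects pairs onto the unit circle, preserving angles", {
  expect_equal(normalize_components(c(0.6, 0.8)), c(0.6, 0.8))
  expect_equal(normalize_components(c(3, 4)), c(0.6, 0.8))
  set.seed(22)
  u <- rnorm(12)
  v <- normalize_components(u)
  expect_equal(atan2(v[seq(2, 12, 2)], v[seq(1, 12, 2)]),
               atan2(u[seq(2, 12, 2)], u[seq(1, 12, 2)]))
  expect_error(normalize_components(c(0, 0, 1, 0)), "degenerate")
})

test_that("closed-loop forecasts stay on the circle and extend the open loop", {
  st <- make_small_setup()
  hist <- collect_history(st$A, st$B, st$inputs, st$targets)
  C <- train_readout(hist, 1e-6)
  warm <- drive(st$A, st$B, numeric(st$spec$size),
                st$u[301:399, , drop = FALSE])
  u_start <- st$u[400, ]
  fc <- forecast(st$A, st$B, C, warm[, 99], u_start, 50, dt = 0.1)
  expect_equal(nrow(fc$components), 50L)
  expect_equal(fc$failure_step, 0L)
  mags <- fc$components[, seq(1, 10, 2)]^2 + fc$components[, seq(2, 10, 2)]^2
  expect_equal(max(abs(mags - 1)), 0, tolerance = 1e-12)
  # first closed-loop output equals the open-loop one-step prediction
  r1 <- reservoir_update(st$A, st$B, warm[, 99], u_start)
  open_loop <- normalize_components(as.numeric(C %*% apply_g(r1)))
  expect_equal(fc$components[1, ], open_loop, tolerance = 1e-12)
})

test_that("training then predicting the training span has small one-step error", {
  st <- make_small_setup()
  hist <- collect_history(st$A, st$B, st$inputs, st$targets)
  C <- train_readout(hist, 1e-6)
  pred <- t(apply(C %*% apply_g(hist$states), 2, normalize_components))
  expect_lt(mean(nmse_series(pred, st$targets)), 0.1)
})
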