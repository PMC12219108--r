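#' Echo state network specification
#'
#' Hyper-parameters of a leakless echo state network. Baselines follow the
#' parameter-error task defaults: 300 nodes, spectral radius 0.4, input
#' scaling 0.15, ridge regularization 1e-6. The internal graph's mean degree
#' is not pinned by those baselines; 3 is the convention of the hybrid
#' reservoir literature this architecture follows.
#'
#' @param size reservoir size D_r (number of nodes).
#' @param spectral_radius target magnitude of the largest eigenvalue of the
#'   internal matrix (>= 0; 0 yields a memoryless, uncoupled reservoir).
#' @param input_scaling half-width of the uniform input-weight distribution.
#' @param mean_degree mean degree of the Erdos-Renyi internal graph.
#' @param ridge_beta ridge regularization strength beta.
#' @param seed integer seed; construction is bit-reproducible given the seed.
#' @return an object of class \code{"reservoir_spec"}.
#' @export
reservoir_spec <- function(size = 300, spectral_radius = 0.4,
                           input_scaling = 0.15, mean_degree = 3,
                           ridge_beta = 1e-6, seed = 1L) {
  size <- as.integer(size)
  stopifnot(size >= 1L, spectral_radius >= 0, input_scaling > 0,
            mean_degree > 0, mean_degree <= size, ridge_beta >= 0)
  structure(list(size = size, spectral_radius = spectral_radius,
                 input_scaling = input_scaling, mean_degree = mean_degree,
                 ridge_beta = ridge_beta, seed = as.integer(seed)),
            class = "reservoir_spec")
}

#' Spectral radius of a matrix
#' @param m a (possibly sparse) square matrix.
#' @return magnitude of the largest eigenvalue.
#' @export
spectral_radius <- function(m) {
  max(Mod(eigen(as.matrix(m), only.values = TRUE)$values))
}

#' Build the internal weight matrix A
#'
#' Erdos-Renyi connectivity with edge probability mean_degree / size, weights
#' Uniform(-1, 1), rescaled so the spectral radius equals the spec value. A
#' spectral radius of 0 returns the zero matrix. If a draw is (numerically)
#' nilpotent, it is redrawn with an advanced seed, up to 10 times.
#'
#' @param spec a \code{"reservoir_spec"}.
#' @return a sparse \code{dgCMatrix} of size D_r x D_r.
#' @export
build_internal <- function(spec) {
  d <- spec$size
  if (spec$spectral_radius == 0)
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(d, d)))
  p <- spec$mean_degree / d
  seed <- derive_seed(spec$seed, 1L)
  for (attempt in seq_len(10L)) {
    set.seed(seed)
    keep <- which(stats::runif(d * d) < p)
    w <- stats::runif(length(keep), -1, 1)
    a <- Matrix::sparseMatrix(i = ((keep - 1L) %% d) + 1L,
                              j = ((keep - 1L) %/% d) + 1L,
                              x = w, dims = c(d, d))
    sr <- if (length(keep)) spectral_radius(a) else 0
    if (sr > 1e-12)
      return(a * (spec$spectral_radius / sr))
    seed <- derive_seed(seed, 97L)
  }
  stop("failed to draw an internal matrix with nonzero spectral radius ",
       "after 10 attempts")
}

#' Build the input weight matrix B
#'
#' One nonzero per row: each reservoir node connects to a single input
#' dimension drawn uniformly, with weight Uniform(-input_scaling,
#' +input_scaling).
#'
#' @param spec a \code{"reservoir_spec"}.
#' @param input_dim number of input dimensions D_in.
#' @return a dense matrix D_r x D_in.
#' @export
build_input <- function(spec, input_dim) {
  stopifnot(input_dim >= 1)
  set.seed(derive_seed(spec$seed, 2L))
  cols <- sample.int(input_dim, spec$size, replace = TRUE)
  w <- stats::runif(spec$size, -spec$input_scaling, spec$input_scaling)
  b <- matrix(0, spec$size, input_dim)
  b[cbind(seq_len(spec$size), cols)] <- w
  b
}

#' One reservoir update
#'
#' r_{t+1} = tanh(A r_t + B u_t); no leak term. Reference implementation in
#' plain R; the sequential drive/forecast loops use the compiled kernels.
#'
#' @param A internal weight matrix.
#' @param B input weight matrix.
#' @param state current activation vector r_t.
#' @param input_vec input vector u_t.
#' @return next activation vector r_{t+1}.
#' @export
reservoir_update <- function(A, B, state, input_vec) {
  if (length(state) != nrow(B) || length(input_vec) != ncol(B))
    stop("dimension mismatch: state has length ", length(state),
         ", input has length ", length(input_vec),
         ", B is ", nrow(B), " x ", ncol(B))
  tanh(as.numeric(A %*% state + B %*% input_vec))
}

#' Readout nonlinearity g
#'
#' Position parity (1-based): odd positions pass through, even positions are
#' squared. Breaks the odd symmetry of tanh activations before the linear
#' readout.
#'
#' @param state_vector numeric vector (or matrix; applied column-wise).
#' @return transformed vector or matrix.
#' @export
apply_g <- function(state_vector) {
  if (is.matrix(state_vector)) {
    even <- seq_len(nrow(state_vector)) %% 2L == 0L
    state_vector[even, ] <- state_vector[even, , drop = FALSE]^2
    state_vector
  } else {
    even <- seq_along(state_vector) %% 2L == 0L
    state_vector[even] <- state_vector[even]^2
    state_vector
  }
}

#' Drive a reservoir feed-forward over an input sequence
#'
#' Iterates the update rule over the rows of \code{inputs}, returning one
#' internal state per input. Used to collect training histories and to warm
#' up (synchronize) the reservoir before a forecast.
#'
#' @param A,B weight matrices.
#' @param initial_state starting activation vector (conventionally zero).
#' @param inputs matrix n x D_in, one input per row.
#' @return matrix D_r x n of internal states (one column per input).
#' @export
drive <- function(A, B, initial_state, inputs) {
  if (ncol(inputs) != ncol(B))
    stop("inputs have ", ncol(inputs), " columns but B expects ", ncol(B))
  drive_cpp(methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix"),
            B, initial_state, inputs)
}

#' Collect a training history for a standard reservoir
#'
#' Drives the reservoir over the training inputs from a zero initial state
#' and pairs the g-transformed states with the one-step-ahead targets.
#'
#' @param A,B weight matrices.
#' @param inputs matrix n_T x D_u of training inputs u_t.
#' @param targets matrix n_T x D_u of next states u_{t+1}.
#' @return a \code{"state_history"}: list with \code{states} (D_r x n_T),
#'   \code{transformed} (R-hat, D_r x n_T) and \code{targets} (D_u x n_T).
#' @export
collect_history <- function(A, B, inputs, targets) {
  stopifnot(nrow(inputs) == nrow(targets))
  states <- drive(A, B, numeric(nrow(B)), inputs)
  structure(list(states = states, transformed = apply_g(states),
                 targets = t(targets)),
            class = "state_history")
}

#' Train the linear readout by ridge regression
#'
#' Minimizes ||C R-hat - U+||^2 + beta ||C||^2. Solved through a QR
#' factorization of the beta-augmented design (rows [R-hat^T; sqrt(beta) I]),
#' not by explicit inversion of the Gram matrix.
#'
#' @param history a \code{"state_history"} (standard or hybrid).
#' @param beta ridge regularization strength (>= 0).
#' @return readout matrix C of size D_u x D_out.
#' @export
train_readout <- function(history, beta) {
  stopifnot(beta >= 0)
  rhat <- history$transformed
  n_t <- ncol(rhat)
  if (n_t < 1) stop("empty training history")
  d_out <- nrow(rhat)
  x <- t(rhat)
  y <- t(history$targets)
  if (beta > 0) {
    x <- rbind(x, diag(sqrt(beta), d_out))
    y <- rbind(y, matrix(0, d_out, ncol(y)))
  }
  qx <- qr(x)
  if (qx$rank < d_out)
    stop("singular readout system (rank ", qx$rank, " < ", d_out,
         "); use beta > 0")
  t(qr.coef(qx, y))
}

#' Phase-component magnitude normalization
#'
#' Projects each (x_i, y_i) pair back to the unit circle:
#' (cos theta_i, sin theta_i) with theta_i = atan2(y_i, x_i). Applied to every
#' closed-loop output so the feedback stays on the phase manifold.
#'
#' @param u numeric vector of length 2N, interleaved components.
#' @return normalized vector; angles are preserved exactly.
#' @export
normalize_components <- function(u) {
  n <- length(u) / 2L
  x <- u[2L * seq_len(n) - 1L]
  y <- u[2L * seq_len(n)]
  m <- sqrt(x^2 + y^2)
  if (any(!is.finite(m)) || any(m < 1e-12))
    stop("degenerate prediction: an oscillator pair has (near-)zero magnitude")
  as.vector(rbind(x / m, y / m))
}

#' Closed-loop (autoregressive) forecast with a standard reservoir
#'
#' Per step: r <- tanh(A r + B u); u <- normalize(C g(r)). The normalized
#' output is both the recorded prediction and the next input. A degenerate
#' normalization truncates the forecast; the failing step is reported in the
#' \code{failure_step} field (0 when none).
#'
#' @param A,B,C weight matrices.
#' @param warm_state reservoir state after driving the warm-up span.
#' @param u_start last warm-up input; the first closed-loop input.
#' @param n_steps number of forecast steps.
#' @param dt time step, s (recorded in the returned trajectory).
#' @return a \code{"component_trajectory"} with fields \code{dt},
#'   \code{components} (n_recorded x D_u) and \code{failure_step}.
#' @export
forecast <- function(A, B, C, warm_state, u_start, n_steps, dt = 0.1) {
  res <- forecast_cpp(methods::as(methods::as(A, "CsparseMatrix"),
                                  "generalMatrix"),
                      B, C, warm_state, u_start, as.integer(n_steps),
                      FALSE, numeric(1), 0, dt)
  structure(list(dt = dt, components = res$states,
                 failure_step = res$failure_step),
            class = "component_trajectory")
}
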