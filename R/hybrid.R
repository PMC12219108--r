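#' Hybrid reservoir specification
#'
#' A hybrid reservoir computer couples an echo state network with a one-step
#' expert ODE integrator (the standard Kuramoto model, possibly with
#' parameter error). The expert's next-step prediction u-tilde_{t+1} is (i)
#' concatenated with the observed state into the reservoir input
#' [u-tilde_{t+1}; u_t] and (ii) passed around the reservoir into the readout
#' state [u-tilde_{t+1}; g(r_{t+1})]. Expert rows always occupy positions
#' 1..D_u of both concatenations.
#'
#' @param reservoir a \code{"reservoir_spec"}.
#' @param knowledge_ratio probability KR in [0, 1] that a reservoir node's
#'   single input connection attaches to the expert prediction block rather
#'   than the observed-state block.
#' @param expert_params a \code{"kuramoto_params"} object — the (typically
#'   perturbed) expert model.
#' @return an object of class \code{"hybrid_spec"}.
#' @export
hybrid_spec <- function(reservoir, knowledge_ratio = 0.5, expert_params) {
  stopifnot(inherits(reservoir, "reservoir_spec"),
            knowledge_ratio >= 0, knowledge_ratio <= 1,
            inherits(expert_params, "kuramoto_params"))
  structure(list(reservoir = reservoir, knowledge_ratio = knowledge_ratio,
                 expert_params = expert_params),
            class = "hybrid_spec")
}

#' Build the hybrid input matrix B (D_r x 2 D_u)
#'
#' One nonzero per row. The column is drawn from the expert block
#' (1..D_u) with probability KR, otherwise from the data block
#' (D_u + 1..2 D_u); the weight is Uniform(-input_scaling, +input_scaling).
#'
#' @param spec a \code{"hybrid_spec"}.
#' @param input_dim observed-state dimension D_u (= 2N).
#' @return dense matrix D_r x 2 * input_dim.
#' @export
build_hybrid_input <- function(spec, input_dim) {
  rs <- spec$reservoir
  set.seed(derive_seed(rs$seed, 2L))
  d <- rs$size
  expert <- stats::runif(d) < spec$knowledge_ratio
  cols <- ifelse(expert,
                 sample.int(input_dim, d, replace = TRUE),
                 input_dim + sample.int(input_dim, d, replace = TRUE))
  w <- stats::runif(d, -rs$input_scaling, rs$input_scaling)
  b <- matrix(0, d, 2L * input_dim)
  b[cbind(seq_len(d), cols)] <- w
  b
}

#' Collect an augmented training history for a hybrid reservoir
#'
#' Per training step: u-tilde_{t+1} = expert_step(u_t); the reservoir is
#' driven with [u-tilde_{t+1}; u_t]; the stacked history column is
#' [u-tilde_{t+1}; g(r_{t+1})] with target u_{t+1}. g is applied to the
#' reservoir rows only — expert rows enter the readout untransformed.
#'
#' @param spec a \code{"hybrid_spec"}.
#' @param A internal matrix; \code{B} hybrid input matrix (D_r x 2 D_u).
#' @param B hybrid input matrix.
#' @param inputs matrix n_T x D_u of training inputs u_t.
#' @param targets matrix n_T x D_u of next states u_{t+1}.
#' @param dt integration step for the expert, s.
#' @return a \code{"state_history"} whose \code{transformed} matrix is the
#'   stacked (D_u + D_r) x n_T augmented history.
#' @export
hybrid_collect <- function(spec, A, B, inputs, targets, dt) {
  stopifnot(nrow(inputs) == nrow(targets))
  ep <- spec$expert_params
  res <- hybrid_drive_cpp(methods::as(methods::as(A, "CsparseMatrix"),
                                      "generalMatrix"),
                          B, numeric(nrow(B)), inputs,
                          ep$natural_frequencies, ep$coupling, dt)
  structure(list(states = res$states,
                 expert_predictions = res$experts,
                 transformed = rbind(res$experts, apply_g(res$states)),
                 targets = t(targets)),
            class = "state_history")
}

#' Train a hybrid readout
#'
#' Ridge regression of the stacked augmented history onto the next-step
#' targets; a single beta regularizes all columns of C, including the
#' expert-passthrough block.
#'
#' @inheritParams hybrid_collect
#' @param beta ridge regularization strength.
#' @return readout matrix C of size D_u x (D_u + D_r).
#' @export
hybrid_train <- function(spec, A, B, inputs, targets, dt, beta) {
  train_readout(hybrid_collect(spec, A, B, inputs, targets, dt), beta)
}

#' Closed-loop forecast with a hybrid reservoir
#'
#' Per step: u-tilde <- expert_step(u); r <- tanh(A r + B [u-tilde; u]);
#' u <- normalize(C [u-tilde; g(r)]). The normalized output is recorded and
#' fed back. The expert prediction entering the readout is the raw integrator
#' output; only the final readout output is normalized.
#'
#' @param spec a \code{"hybrid_spec"}.
#' @param A,B,C weight matrices (B hybrid-shaped, C is D_u x (D_u + D_r)).
#' @param warm_state reservoir state after the hybrid warm-up.
#' @param u_start last warm-up state (first closed-loop input).
#' @param n_steps forecast length in steps.
#' @param dt time step, s.
#' @return a \code{"component_trajectory"} with \code{failure_step}.
#' @export
hybrid_forecast <- function(spec, A, B, C, warm_state, u_start, n_steps,
                            dt = 0.1) {
  ep <- spec$expert_params
  res <- forecast_cpp(methods::as(methods::as(A, "CsparseMatrix"),
                                  "generalMatrix"),
                      B, C, warm_state, u_start, as.integer(n_steps), TRUE,
                      ep$natural_frequencies, ep$coupling, dt)
  structure(list(dt = dt, components = res$states,
                 failure_step = res$failure_step),
            class = "component_trajectory")
}

#' Warm up a hybrid reservoir along a trajectory span
#'
#' Drives the reservoir feed-forward, computing the expert prediction at
#' every step to form the concatenated inputs; outputs are discarded and the
#' final internal state is returned.
#'
#' @inheritParams hybrid_collect
#' @param inputs matrix n x D_u of warm-up states.
#' @return final reservoir state vector.
#' @export
hybrid_warmup <- function(spec, A, B, inputs, dt) {
  ep <- spec$expert_params
  res <- hybrid_drive_cpp(methods::as(methods::as(A, "CsparseMatrix"),
                                      "generalMatrix"),
                          B, numeric(nrow(B)), inputs,
                          ep$natural_frequencies, ep$coupling, dt)
  res$states[, ncol(res$states)]
}

#' Pure expert (base ODE model) control forecast
#'
#' Iterates the expert one-step integrator from the test initial condition
#' with the same per-step magnitude normalization the reservoirs apply — the
#' "base ODE model" control arm, no reservoir involved. Numerically identical
#' to a hybrid forecast with the passthrough readout C = [I | 0].
#'
#' @param params expert \code{"kuramoto_params"} (typically perturbed).
#' @param u_start initial components (length 2N).
#' @param n_steps forecast length in steps.
#' @param dt time step, s.
#' @return a \code{"component_trajectory"} with \code{failure_step}.
#' @export
ode_control_forecast <- function(params, u_start, n_steps, dt = 0.1) {
  res <- expert_forecast_cpp(u_start, as.integer(n_steps),
                             params$natural_frequencies, params$coupling, dt)
  structure(list(dt = dt, components = res$states,
                 failure_step = res$failure_step),
            class = "component_trajectory")
}
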