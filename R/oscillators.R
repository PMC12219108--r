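#' Standard Kuramoto model parameters
#'
#' Bundle the parameters of an all-to-all coupled network of Kuramoto phase
#' oscillators: dtheta_i/dt = omega_i + (K/N) sum_j sin(theta_j - theta_i).
#'
#' @param n_oscillators number of oscillators N (positive integer).
#' @param natural_frequencies numeric vector of length N, natural frequencies
#'   omega_i in rad/s.
#' @param coupling global coupling strength K in rad/s.
#' @return an object of class \code{"kuramoto_params"}.
#' @export
kuramoto_params <- function(n_oscillators, natural_frequencies, coupling) {
  n_oscillators <- as.integer(n_oscillators)
  stopifnot(length(n_oscillators) == 1L, n_oscillators >= 1L)
  natural_frequencies <- as.numeric(natural_frequencies)
  if (length(natural_frequencies) != n_oscillators)
    stop("natural_frequencies must have length n_oscillators (", n_oscillators, ")")
  stopifnot(all(is.finite(natural_frequencies)),
            length(coupling) == 1L, is.finite(coupling))
  structure(list(n_oscillators = n_oscillators,
                 natural_frequencies = natural_frequencies,
                 coupling = as.numeric(coupling)),
            class = "kuramoto_params")
}

#' Bi-harmonic Kuramoto model parameters
#'
#' Parameters of the extended Kuramoto model with a second harmonic in the
#' coupling: dtheta_i/dt = omega_i +
#' (K/N) sum_j [sin(theta_j - theta_i + gamma1) +
#'              a sin(2(theta_j - theta_i) + gamma2)].
#' The phase shifts gamma1, gamma2 and the second-harmonic scale a select
#' regimes (multi-cluster synchrony, heteroclinic cycles, self-consistent
#' partial synchrony) that the first-harmonic model cannot produce.
#'
#' @inheritParams kuramoto_params
#' @param gamma1,gamma2 coupling phase shifts, rad.
#' @param second_harmonic_scale scale a of the second harmonic (dimensionless).
#' @param freq_center,freq_width center mu and width (> 0) of the Lorentzian
#'   (Cauchy) distribution the natural frequencies are drawn from, rad/s.
#'   Recorded for provenance; the draw itself happens in [sample_regime()].
#' @return an object of class \code{"biharmonic_params"}.
#' @export
biharmonic_params <- function(n_oscillators, natural_frequencies, coupling,
                              gamma1, gamma2, second_harmonic_scale,
                              freq_center = 0, freq_width = 0.01) {
  base <- kuramoto_params(n_oscillators, natural_frequencies, coupling)
  stopifnot(is.finite(gamma1), is.finite(gamma2),
            is.finite(second_harmonic_scale),
            is.finite(freq_center), is.finite(freq_width), freq_width > 0)
  base$gamma1 <- as.numeric(gamma1)
  base$gamma2 <- as.numeric(gamma2)
  base$second_harmonic_scale <- as.numeric(second_harmonic_scale)
  base$freq_center <- as.numeric(freq_center)
  base$freq_width <- as.numeric(freq_width)
  class(base) <- "biharmonic_params"
  base
}

#' Reduce bi-harmonic parameters to the standard Kuramoto core
#'
#' Extracts N, omega and K. This is the expert model used by the hybrid
#' reservoir in the residual-physics task: the structural second-harmonic
#' term is deliberately absent.
#'
#' @param params a \code{"biharmonic_params"} or \code{"kuramoto_params"} object.
#' @return a \code{"kuramoto_params"} object.
#' @export
as_kuramoto <- function(params) {
  kuramoto_params(params$n_oscillators, params$natural_frequencies,
                  params$coupling)
}

regime_names <- list(
  parameter_error = c("synchrony", "asynchrony", "multi_frequency"),
  residual_physics = c("synchrony", "asynchrony", "heteroclinic_cycles",
                       "partial_synchrony")
)

#' Sample ground-truth parameters for a named dynamical regime
#'
#' Parameter-error task regimes (standard Kuramoto, N = 5, omega ~ U(-1, 1)):
#' synchrony (K = 4), asynchrony (K = 1) and multi-frequency (K = 2, with the
#' fifth oscillator's frequency set to z(3 + w), w ~ U(0, 1), z a random sign).
#' Residual-physics regimes (bi-harmonic Kuramoto, N = 10,
#' omega ~ Cauchy(0, width), gamma2 = pi, a = 0.2): synchrony
#' (K = 1, gamma1 = 2*pi, width 0.01), asynchrony (K = 5, gamma1 = pi,
#' width 0.05), heteroclinic cycles (K = 1, gamma1 = 1.3) and partial
#' synchrony (K = 1, gamma1 = 1.5).
#'
#' @param task \code{"parameter_error"} or \code{"residual_physics"}.
#' @param regime_name regime name, see Details.
#' @param seed integer seed; the draw is fully determined by
#'   (task, regime_name, seed).
#' @return a \code{"kuramoto_params"} or \code{"biharmonic_params"} object.
#' @export
sample_regime <- function(task = c("parameter_error", "residual_physics"),
                          regime_name, seed) {
  task <- match.arg(task)
  valid <- regime_names[[task]]
  if (!regime_name %in% valid)
    stop("unknown regime '", regime_name, "' for task '", task,
         "'; valid regimes: ", paste(valid, collapse = ", "))
  set.seed(as.integer(seed))
  if (task == "parameter_error") {
    n <- 5L
    omega <- stats::runif(n, -1, 1)
    k <- switch(regime_name, synchrony = 4.0, asynchrony = 1.0,
                multi_frequency = 2.0)
    if (regime_name == "multi_frequency") {
      w <- stats::runif(1, 0, 1)
      z <- sample(c(-1, 1), 1)
      omega[n] <- z * (3.0 + w)
    }
    kuramoto_params(n, omega, k)
  } else {
    n <- 10L
    row <- switch(regime_name,
      synchrony          = list(width = 0.01, k = 1.0, gamma1 = 2 * pi),
      asynchrony         = list(width = 0.05, k = 5.0, gamma1 = pi),
      heteroclinic_cycles = list(width = 0.01, k = 1.0, gamma1 = 1.3),
      partial_synchrony  = list(width = 0.01, k = 1.0, gamma1 = 1.5))
    omega <- stats::rcauchy(n, location = 0, scale = row$width)
    biharmonic_params(n, omega, row$k, gamma1 = row$gamma1, gamma2 = pi,
                      second_harmonic_scale = 0.2, freq_center = 0,
                      freq_width = row$width)
  }
}

#' Phase velocities of the standard Kuramoto model
#'
#' @param phases numeric vector of N phases, rad.
#' @param params a \code{"kuramoto_params"} object.
#' @return numeric vector of dtheta/dt, rad/s.
#' @export
kuramoto_rhs <- function(phases, params) {
  n <- params$n_oscillators
  if (length(phases) != n)
    stop("phases must have length ", n, ", got ", length(phases))
  diff <- outer(phases, phases, function(a, b) sin(a - b)) # [j, i] = sin(th_j - th_i)
  params$natural_frequencies + params$coupling / n * colSums(diff)
}

#' Phase velocities of the bi-harmonic Kuramoto model
#'
#' @inheritParams kuramoto_rhs
#' @param params a \code{"biharmonic_params"} object.
#' @return numeric vector of dtheta/dt, rad/s. The j = i self-term is kept
#'   exactly as the model is written; it contributes
#'   sin(gamma1) + a sin(gamma2) per oscillator (nonzero unless the shifts
#'   are multiples of pi).
#' @export
biharmonic_rhs <- function(phases, params) {
  n <- params$n_oscillators
  if (length(phases) != n)
    stop("phases must have length ", n, ", got ", length(phases))
  dphi <- outer(phases, phases, function(a, b) a - b) # [j, i] = th_j - th_i
  s <- sin(dphi + params$gamma1) +
    params$second_harmonic_scale * sin(2 * dphi + params$gamma2)
  params$natural_frequencies + params$coupling / n * colSums(s)
}

#' Phase-component velocities of the standard Kuramoto model
#'
#' The model in the (x, y) = (cos theta, sin theta) projection used by the
#' reservoirs, one ODE pair per oscillator:
#' dx_i/dt = -omega_i y_i - (K y_i / N) sum_j (y_j x_i - x_j y_i),
#' dy_i/dt =  omega_i x_i + (K x_i / N) sum_j (y_j x_i - x_j y_i).
#' Components are interleaved per oscillator: (x1, y1, x2, y2, ...).
#'
#' @param components numeric vector of length 2N.
#' @param params a \code{"kuramoto_params"} object.
#' @return numeric vector of length 2N.
#' @export
kuramoto_component_rhs <- function(components, params) {
  n <- params$n_oscillators
  if (length(components) != 2L * n)
    stop("components must have length ", 2L * n, ", got ", length(components))
  x <- components[2L * seq_len(n) - 1L]
  y <- components[2L * seq_len(n)]
  k_over_n <- params$coupling / n
  s <- x * sum(y) - y * sum(x)  # sum_j (y_j x_i - x_j y_i)
  dx <- -params$natural_frequencies * y - k_over_n * y * s
  dy <- params$natural_frequencies * x + k_over_n * x * s
  as.vector(rbind(dx, dy))
}

#' Wrap angles to [-pi, pi)
#' @param theta numeric vector or matrix of angles, rad.
#' @return wrapped angles.
#' @export
wrap_phase <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w >= pi] <- w[w >= pi] - 2 * pi  # rounding edge: keep [-pi, pi)
  w
}

#' Phase <-> phase-component transforms
#'
#' `phases_to_components` maps each phase to (cos theta, sin theta),
#' interleaved per oscillator; `components_to_phases` inverts it with the
#' two-argument arctangent. The round trip is the identity on [-pi, pi).
#'
#' @param phases numeric vector of N phases or matrix (steps x N).
#' @return matrix or vector of 2N interleaved components.
#' @export
phases_to_components <- function(phases) {
  if (is.matrix(phases)) {
    n <- ncol(phases)
    out <- matrix(0, nrow(phases), 2L * n)
    out[, 2L * seq_len(n) - 1L] <- cos(phases)
    out[, 2L * seq_len(n)] <- sin(phases)
    colnames(out) <- as.vector(rbind(paste0("x", seq_len(n)),
                                     paste0("y", seq_len(n))))
    out
  } else {
    as.vector(rbind(cos(phases), sin(phases)))
  }
}

#' @rdname phases_to_components
#' @param components numeric vector of 2N interleaved components or matrix
#'   (steps x 2N).
#' @export
components_to_phases <- function(components) {
  to_phase <- function(x, y) {
    if (any(x == 0 & y == 0))
      stop("degenerate state: an oscillator pair is at the origin")
    atan2(y, x)
  }
  if (is.matrix(components)) {
    n <- ncol(components) / 2L
    out <- to_phase(components[, 2L * seq_len(n) - 1L, drop = FALSE],
                    components[, 2L * seq_len(n), drop = FALSE])
    dimnames(out) <- NULL
    out
  } else {
    n <- length(components) / 2L
    to_phase(components[2L * seq_len(n) - 1L], components[2L * seq_len(n)])
  }
}

#' Integrate an oscillator network
#'
#' Fixed-step 4th-order Runge-Kutta in phase coordinates; the state is wrapped
#' to [-pi, pi) after every step (the right-hand sides are 2*pi-periodic, so
#' wrapping whole steps is exact). Deterministic.
#'
#' @param params \code{"kuramoto_params"} or \code{"biharmonic_params"}.
#' @param initial_phases numeric vector of N initial phases, rad.
#' @param dt time step in s (> 0).
#' @param n_steps number of steps (>= 1); the output holds n_steps + 1 states
#'   including the initial one.
#' @return a \code{"phase_trajectory"}: list with \code{dt} and \code{phases}
#'   (matrix (n_steps + 1) x N, wrapped to [-pi, pi)).
#' @export
integrate_oscillators <- function(params, initial_phases, dt, n_steps) {
  stopifnot(dt > 0, n_steps >= 1)
  if (length(initial_phases) != params$n_oscillators)
    stop("initial_phases must have length ", params$n_oscillators)
  bih <- inherits(params, "biharmonic_params")
  phases <- rk4_integrate_phases(
    initial_phases, params$natural_frequencies, params$coupling,
    dt, as.integer(n_steps), bih,
    if (bih) params$gamma1 else 0, if (bih) params$gamma2 else 0,
    if (bih) params$second_harmonic_scale else 0)
  structure(list(dt = dt, phases = phases), class = "phase_trajectory")
}

#' Convert a phase trajectory to phase components
#'
#' @param trajectory a \code{"phase_trajectory"}.
#' @return a \code{"component_trajectory"}: list with \code{dt} and
#'   \code{components} (matrix n_states x 2N, interleaved per oscillator).
#' @export
as_component_trajectory <- function(trajectory) {
  structure(list(dt = trajectory$dt,
                 components = phases_to_components(trajectory$phases)),
            class = "component_trajectory")
}

#' Multiplicative parameter error
#'
#' Applies p -> (1 + xi) p with xi ~ Normal(0, sigma^2): the coupling K is
#' scaled once with sigma_coupling, each natural frequency independently with
#' sigma_frequency. Any bi-harmonic fields are untouched. Draws come from the
#' current RNG state (seed the stream before calling for reproducibility).
#'
#' @param params \code{"kuramoto_params"} or \code{"biharmonic_params"}.
#' @param sigma_coupling,sigma_frequency nonnegative error standard deviations.
#' @return params with perturbed coupling and frequencies.
#' @export
perturb_params <- function(params, sigma_coupling = 0.05,
                           sigma_frequency = 0.05) {
  stopifnot(sigma_coupling >= 0, sigma_frequency >= 0)
  out <- params
  if (sigma_coupling > 0)
    out$coupling <- params$coupling * (1 + stats::rnorm(1, 0, sigma_coupling))
  if (sigma_frequency > 0)
    out$natural_frequencies <- params$natural_frequencies *
      (1 + stats::rnorm(params$n_oscillators, 0, sigma_frequency))
  out
}

#' One expert integration step in phase-component coordinates
#'
#' A single RK4 step of the component-form standard Kuramoto model, the
#' "expert" prediction embedded in the hybrid reservoir. No magnitude
#' renormalization is applied here; that is owned by the reservoir feedback
#' loop.
#'
#' @param params a \code{"kuramoto_params"} object (the expert model).
#' @param u numeric vector of length 2N, interleaved components.
#' @param dt step size, s.
#' @return numeric vector of length 2N.
#' @export
expert_step <- function(params, u, dt) {
  if (length(u) != 2L * params$n_oscillators)
    stop("u must have length ", 2L * params$n_oscillators)
  as.numeric(expert_step_cpp(u, params$natural_frequencies,
                             params$coupling, dt))
}

#' Kuramoto order parameter r(t)
#'
#' r(t) = |sum_j exp(i theta_j)| / N; 1 at full synchrony, near 0 for
#' incoherent phases.
#'
#' @param phases matrix (steps x N) or vector of phases.
#' @return numeric vector of r(t).
#' @export
order_parameter <- function(phases) {
  if (!is.matrix(phases)) phases <- matrix(phases, nrow = 1)
  Mod(rowSums(exp(1i * phases))) / ncol(phases)
}
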