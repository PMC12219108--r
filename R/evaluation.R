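#' Trajectory segmentation plan
#'
#' Layout of a long ground-truth trajectory into a training span, a gap, and
#' repeated (warm-up, test, gap) segments. The default is the shared
#' protocol: dt = 0.1 s, 1000 training steps, a 1000-step gap, then 20
#' segments of 100 warm-up + 2500 test steps with 400-step gaps — 62,000
#' steps (6200 s) in total. Shrink \code{n_segments} for desk-scale runs.
#'
#' @param dt time step, s.
#' @param train_len,post_train_gap,warmup_len,test_len,inter_gap span lengths
#'   in steps.
#' @param n_segments number of warm-up/test segments.
#' @return an object of class \code{"segmentation_plan"}.
#' @export
segmentation_plan <- function(dt = 0.1, train_len = 1000,
                              post_train_gap = 1000, n_segments = 20,
                              warmup_len = 100, test_len = 2500,
                              inter_gap = 400) {
  stopifnot(dt > 0, train_len >= 1, post_train_gap >= 0, n_segments >= 1,
            warmup_len >= 2, test_len >= 1, inter_gap >= 0)
  structure(list(dt = dt, train_len = as.integer(train_len),
                 post_train_gap = as.integer(post_train_gap),
                 n_segments = as.integer(n_segments),
                 warmup_len = as.integer(warmup_len),
                 test_len = as.integer(test_len),
                 inter_gap = as.integer(inter_gap)),
            class = "segmentation_plan")
}

#' Total steps required by a segmentation plan
#' @param plan a \code{"segmentation_plan"}.
#' @return required trajectory length in steps (the default plan needs 62,000).
#' @export
total_steps <- function(plan) {
  plan$train_len + plan$post_train_gap +
    plan$n_segments * (plan$warmup_len + plan$test_len + plan$inter_gap)
}

#' Segment a component trajectory
#'
#' Splits the trajectory's state rows into the training span and the
#' warm-up/test segments. In 0-based half-open terms the training span is
#' [0, train_len) and segment i's warm-up starts at
#' train_len + post_train_gap + i * (warmup_len + test_len + inter_gap), with
#' the test span immediately following; all spans are disjoint. Training
#' targets are the inputs shifted one step ahead (the first target is the
#' second training sample; the last target is the state just after the
#' training span).
#'
#' @param trajectory a \code{"component_trajectory"} (or any list with a
#'   \code{components} state matrix).
#' @param plan a \code{"segmentation_plan"}.
#' @return list with \code{train_inputs}, \code{train_targets} (matrices
#'   train_len x D_u) and \code{segments}, a list of
#'   \code{list(warmup, test)} state matrices.
#' @export
segment_trajectory <- function(trajectory, plan) {
  u <- trajectory$components
  need <- total_steps(plan) + 1L # +1: targets extend one step past the span
  if (nrow(u) < need)
    stop("trajectory too short: ", nrow(u), " states, need at least ", need)
  train_inputs <- u[seq_len(plan$train_len), , drop = FALSE]
  train_targets <- u[seq_len(plan$train_len) + 1L, , drop = FALSE]
  block <- plan$warmup_len + plan$test_len + plan$inter_gap
  segments <- lapply(seq_len(plan$n_segments) - 1L, function(i) {
    w0 <- plan$train_len + plan$post_train_gap + i * block # 0-based start
    list(warmup = u[(w0 + 1L):(w0 + plan$warmup_len), , drop = FALSE],
         test = u[(w0 + plan$warmup_len + 1L):(w0 + plan$warmup_len +
                                                 plan$test_len), ,
                  drop = FALSE])
  })
  list(train_inputs = train_inputs, train_targets = train_targets,
       segments = segments)
}

#' Normalized mean square error series
#'
#' NMSE(t) = ||u(t) - u*(t)|| / <||u(t)||^2>^(1/2), where u* is the
#' prediction, u the ground truth, and the denominator averages the squared
#' state norm over the test span's ground truth. For unit-magnitude phase
#' components the denominator is exactly sqrt(N). A truncated prediction is
#' scored on its available prefix.
#'
#' @param predicted matrix n_pred x D_u of predictions (n_pred <= n_truth).
#' @param truth matrix n_truth x D_u of ground-truth states.
#' @return numeric vector of length n_pred.
#' @export
nmse_series <- function(predicted, truth) {
  if (ncol(predicted) != ncol(truth))
    stop("shape mismatch: predicted has ", ncol(predicted),
         " columns, truth has ", ncol(truth))
  if (nrow(predicted) > nrow(truth))
    stop("prediction longer than ground truth (", nrow(predicted), " > ",
         nrow(truth), ")")
  denom <- sqrt(mean(rowSums(truth^2)))
  if (nrow(predicted) == 0L) return(numeric(0))
  err <- predicted - truth[seq_len(nrow(predicted)), , drop = FALSE]
  sqrt(rowSums(err^2)) / denom
}

#' Valid time of a forecast
#'
#' t* = max{ t : NMSE(tau) <= epsilon for all tau <= t }: the longest prefix
#' during which the error stays below the threshold. Forecast step k
#' (1-based) maps to time k * dt; an exceedance at the first step gives 0.
#'
#' @param nmse numeric NMSE series (one value per forecast step).
#' @param epsilon error threshold (> 0); 0.4 throughout the residual task.
#' @param dt time step, s.
#' @return valid time in seconds.
#' @export
valid_time <- function(nmse, epsilon = 0.4, dt = 0.1) {
  stopifnot(epsilon > 0)
  bad <- which(nmse > epsilon)
  k <- if (length(bad)) bad[1L] - 1L else length(nmse)
  k * dt
}

#' Check that a simulated trajectory exhibits its named regime
#'
#' The regime presets draw natural frequencies at random (Cauchy draws for
#' the bi-harmonic model are heavy-tailed and are deliberately not
#' truncated), so an individual realization can fail to display the dynamics
#' its name promises — e.g. a "synchrony" draw containing one natural
#' frequency far outside the entrainment range of the coupling. This check
#' classifies the post-transient Kuramoto order parameter r(t): synchrony
#' requires r to stay at phase-locked levels (min r >= 0.95); the
#' residual-task asynchronous regime requires incoherence on average
#' (mean r <= 0.6); heteroclinic cycles and partial synchrony require
#' intermediate coherence (mean r in [0.2, 0.97] and [0.05, 0.9]). Regimes
#' whose frequency draws have bounded support (the parameter-error task's
#' asynchronous and multi-frequency rows) qualify by construction. The
#' transient (first quarter of the trajectory) is discarded.
#' [run_ensemble()] uses this to advance deterministically to the next
#' seeded realization when a draw misses its regime.
#'
#' @param phases matrix (steps x N) of simulated phases.
#' @param task,regime_name regime identity, see [sample_regime()].
#' @return TRUE if the trajectory is a valid realization of the regime.
#' @export
regime_ok <- function(phases, task, regime_name) {
  post <- phases[-seq_len(floor(nrow(phases) / 4)), , drop = FALSE]
  r <- order_parameter(post)
  switch(regime_name,
         synchrony = min(r) >= 0.95,
         asynchrony = task != "residual_physics" || mean(r) <= 0.6,
         heteroclinic_cycles = mean(r) >= 0.2 && mean(r) <= 0.97,
         partial_synchrony = mean(r) >= 0.05 && mean(r) <= 0.9,
         TRUE)
}

#' Score one forecast against the ground truth
#'
#' @param prediction a \code{"component_trajectory"} (possibly truncated).
#' @param truth matrix of ground-truth test states.
#' @param epsilon valid-time threshold.
#' @param dt time step, s.
#' @return a \code{"forecast_result"}: list with \code{nmse_series},
#'   \code{mean_nmse}, \code{valid_time} (s) and \code{failure_step}.
#' @export
evaluate_forecast <- function(prediction, truth, epsilon = 0.4, dt = 0.1) {
  series <- nmse_series(prediction$components, truth)
  structure(list(nmse_series = series,
                 mean_nmse = if (length(series)) mean(series) else NA_real_,
                 valid_time = valid_time(series, epsilon, dt),
                 failure_step = prediction$failure_step),
            class = "forecast_result")
}

#' Run an ensemble of reservoir (or control) forecasts
#'
#' The shared test procedure: simulate the ground-truth regime, train one
#' model per instantiation on the training span, warm-start and forecast
#' every test segment, and summarize the chosen metric per instantiation and
#' across the ensemble. The parameter-error task uses 3 independently seeded
#' ground-truth realizations (3 x 20 = 60 forecasts per instantiation); the
#' residual-physics task uses 1 (20 forecasts). Each instantiation draws a
#' fresh reservoir and fresh multiplicative parameter error for its expert.
#'
#' @param task \code{"parameter_error"} or \code{"residual_physics"}.
#' @param regime_name regime name, see [sample_regime()].
#' @param model_kind \code{"standard"}, \code{"hybrid"} or
#'   \code{"ode_control"}.
#' @param config named list overriding baseline settings, see
#'   [baseline_config()].
#' @param n_instantiations ensemble size (40 in the full protocol).
#' @param metric \code{"valid_time"} (s) or \code{"mean_nmse"}.
#' @param plan a \code{"segmentation_plan"}.
#' @param base_seed integer seed for the whole ensemble.
#' @param n_realizations number of ground-truth realizations (defaults by
#'   task: 3 for parameter error, 1 for residual physics).
#' @return a \code{"forecast_ensemble_summary"}: per-instantiation means,
#'   grand mean and sd, counts, and the resolved configuration.
#' @export
run_ensemble <- function(task = c("parameter_error", "residual_physics"),
                         regime_name,
                         model_kind = c("standard", "hybrid", "ode_control"),
                         config = list(), n_instantiations = 40,
                         metric = c("valid_time", "mean_nmse"),
                         plan = segmentation_plan(), base_seed = 1L,
                         n_realizations = NULL) {
  task <- match.arg(task)
  model_kind <- match.arg(model_kind)
  metric <- match.arg(metric)
  cfg <- utils::modifyList(baseline_config(task), config)
  if (is.null(n_realizations))
    n_realizations <- if (task == "parameter_error") 3L else 1L

  realizations <- lapply(seq_len(n_realizations), function(k) {
    traj <- NULL
    for (attempt in 0:9) {
      seed_k <- derive_seed(base_seed, 101L, k, attempt)
      truth <- sample_regime(task, regime_name, seed = seed_k)
      set.seed(derive_seed(seed_k, 7L))
      init <- stats::runif(truth$n_oscillators, -pi, pi)
      cand <- integrate_oscillators(truth, init, plan$dt, total_steps(plan))
      if (regime_ok(cand$phases, task, regime_name)) {
        traj <- cand
        break
      }
    }
    if (is.null(traj))
      stop("could not realize regime '", regime_name,
           "' within 10 seeded attempts")
    spans <- segment_trajectory(as_component_trajectory(traj), plan)
    expert_base <- if (task == "parameter_error") truth else as_kuramoto(truth)
    list(truth = truth, expert_base = expert_base, spans = spans)
  })
  d_u <- 2L * realizations[[1L]]$truth$n_oscillators

  forecast_segment <- function(model, seg) {
    n_w <- nrow(seg$warmup)
    warm_inputs <- seg$warmup[seq_len(n_w - 1L), , drop = FALSE]
    u_start <- seg$warmup[n_w, ]
    pred <- switch(model$kind,
      standard = {
        r <- drive(model$A, model$B, numeric(nrow(model$B)), warm_inputs)
        forecast(model$A, model$B, model$C, r[, ncol(r)], u_start,
                 plan$test_len, plan$dt)
      },
      hybrid = {
        r <- hybrid_warmup(model$spec, model$A, model$B, warm_inputs, plan$dt)
        hybrid_forecast(model$spec, model$A, model$B, model$C, r, u_start,
                        plan$test_len, plan$dt)
      },
      ode_control = ode_control_forecast(model$expert, u_start,
                                         plan$test_len, plan$dt))
    evaluate_forecast(pred, seg$test, cfg$epsilon, plan$dt)[[metric]]
  }

  per_inst <- vapply(seq_len(n_instantiations), function(i) {
    rspec <- reservoir_spec(size = cfg$size,
                            spectral_radius = cfg$spectral_radius,
                            input_scaling = cfg$input_scaling,
                            mean_degree = cfg$mean_degree,
                            ridge_beta = cfg$ridge_beta,
                            seed = derive_seed(base_seed, 303L, i))
    A <- if (model_kind != "ode_control") build_internal(rspec)
    vals <- unlist(lapply(seq_len(n_realizations), function(k) {
      rr <- realizations[[k]]
      set.seed(derive_seed(base_seed, 202L, i, k))
      expert <- perturb_params(rr$expert_base, cfg$sigma_coupling,
                               cfg$sigma_frequency)
      model <- switch(model_kind,
        standard = {
          B <- build_input(rspec, d_u)
          C <- train_readout(collect_history(A, B, rr$spans$train_inputs,
                                             rr$spans$train_targets),
                             cfg$ridge_beta)
          list(kind = "standard", A = A, B = B, C = C)
        },
        hybrid = {
          hs <- hybrid_spec(rspec, cfg$knowledge_ratio, expert)
          B <- build_hybrid_input(hs, d_u)
          C <- hybrid_train(hs, A, B, rr$spans$train_inputs,
                            rr$spans$train_targets, plan$dt, cfg$ridge_beta)
          list(kind = "hybrid", spec = hs, A = A, B = B, C = C)
        },
        ode_control = list(kind = "ode_control", expert = expert))
      vapply(rr$spans$segments, function(seg) forecast_segment(model, seg),
             numeric(1))
    }))
    mean(vals, na.rm = TRUE)
  }, numeric(1))

  structure(list(per_instantiation_means = per_inst,
                 grand_mean = mean(per_inst),
                 grand_sd = stats::sd(per_inst),
                 n_instantiations = n_instantiations,
                 n_forecasts_per_instantiation =
                   n_realizations * plan$n_segments,
                 metric = metric, task = task, regime_name = regime_name,
                 model_kind = model_kind, config = cfg,
                 base_seed = as.integer(base_seed)),
            class = "forecast_ensemble_summary")
}

#' @method print forecast_ensemble_summary
#' @export
print.forecast_ensemble_summary <- function(x, ...) {
  cat(sprintf(
    "Forecast ensemble: %s / %s / %s\n  %d instantiations x %d forecasts; %s = %.4g +/- %.4g\n",
    x$task, x$regime_name, x$model_kind, x$n_instantiations,
    x$n_forecasts_per_instantiation, x$metric, x$grand_mean, x$grand_sd))
  invisible(x)
}
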