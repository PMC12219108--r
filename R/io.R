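#' Export a component trajectory as delimited text
#'
#' CSV with a \code{time} column followed by interleaved component columns
#' x1, y1, ..., xN, yN.
#'
#' @param trajectory a \code{"component_trajectory"}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  u <- trajectory$components
  n <- ncol(u) / 2L
  df <- data.frame(time = (seq_len(nrow(u)) - 1L) * trajectory$dt, u)
  names(df) <- c("time", as.vector(rbind(paste0("x", seq_len(n)),
                                         paste0("y", seq_len(n)))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Import a component trajectory from delimited text
#'
#' Reads the format written by [write_trajectory_csv()]; dt is recovered from
#' the time column.
#'
#' @param path CSV file path.
#' @return a \code{"component_trajectory"}.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  if (names(df)[1L] != "time") stop("expected a leading 'time' column")
  dt <- if (nrow(df) > 1L) df$time[2L] - df$time[1L] else NA_real_
  structure(list(dt = dt,
                 components = as.matrix(df[, -1L, drop = FALSE])),
            class = "component_trajectory")
}

#' Persist an ensemble summary as CSV plus a JSON sidecar
#'
#' One CSV row per instantiation; the sidecar records the resolved
#' configuration, seeds and grand statistics so the run can be reproduced
#' exactly.
#'
#' @param summary a \code{"forecast_ensemble_summary"}.
#' @param path output CSV path; the sidecar is written next to it with a
#'   \code{.json} extension.
#' @return the CSV path, invisibly.
#' @export
write_ensemble_summary <- function(summary, path) {
  df <- data.frame(instantiation = seq_along(summary$per_instantiation_means),
                   metric = summary$metric,
                   metric_value = summary$per_instantiation_means)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(task = summary$task, regime = summary$regime_name,
         model_kind = summary$model_kind, metric = summary$metric,
         n_instantiations = summary$n_instantiations,
         n_forecasts_per_instantiation =
           summary$n_forecasts_per_instantiation,
         base_seed = summary$base_seed, config = summary$config,
         grand_mean = summary$grand_mean, grand_sd = summary$grand_sd),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
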