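#' Derive a child seed from a base seed and index path
#'
#' Splitmix-style integer hash combining the base seed with any number of
#' integer indices (sweep index, instantiation index, realization index, ...).
#' Keeps independent experiment arms on decorrelated RNG streams while staying
#' fully determined by the base seed. All arithmetic stays below 2^53 so the
#' result is exact in double precision, and the returned seed is a
#' nonnegative 32-bit integer.
#'
#' @param base integer base seed.
#' @param ... integer indices identifying the child stream.
#' @return a single integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(base, ...) {
  m <- 2147483647 # 2^31 - 1
  x <- as.numeric(base) %% m
  for (k in c(...)) {
    k <- as.numeric(k) %% m
    # two mixed congruential rounds per index; multipliers < 2^22 keep the
    # products exactly representable
    x <- (x * 69069 + k + 1) %% m
    x <- (x * 40503 + (k * 2654435) %% m + 101) %% m
  }
  as.integer(x)
}
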