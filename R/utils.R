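#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic stream splitting: every stochastic stage of a study (pair
#' generation, each null mode's Monte Carlo run, the genome simulation)
#' draws its own seed from the master seed and a tuple of small integer
#' indices, so that the two null models are always compared on identical
#' data and any single stage can be re-run in isolation.
#'
#' The map is a Lehmer-style multiplicative hash iterated over the indices,
#' modulo 2^31 - 1, so derived seeds stay valid 32-bit R seeds.
#'
#' @param seed master seed (integer).
#' @param ... one or more non-negative integer indices identifying the stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 3)
#' derive_seed(1, 3, 2)
derive_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1, all(idx >= 0))
  m <- 2147483647
  x <- (as.numeric(seed) %% m + m) %% m
  for (i in idx) {
    x <- (x * 48271 + as.numeric(i) + 1) %% m
    x <- (x * 48271 + 11) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

# Evaluate expr under a fixed seed (restoring RNG state), or under the
# current RNG stream when seed is NULL.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(v - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
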