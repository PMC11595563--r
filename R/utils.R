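#' Derive independent per-stage seeds from one master seed
#'
#' A splitmix-style integer hash chain: each stage gets a seed that is a
#' deterministic function of the master seed and the stage index, so stages
#' can be rerun independently without sharing RNG streams.
#'
#' @param seed master seed (single integer).
#' @param n number of stage seeds to derive.
#' @return integer vector of length `n`, each in `[0, 2^31 - 1]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  x <- as.double(seed) %% 2147483647
  out <- numeric(n)
  for (i in seq_len(n)) {
    # 64-bit-safe multiplicative mixing in double precision (exact below 2^53)
    x <- (x * 48271 + i * 2654435761) %% 2147483647
    x <- (x * 69621) %% 2147483647
    out[i] <- x
  }
  as.integer(out)
}

logistic <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ps <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
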