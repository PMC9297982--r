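#' @importFrom stats rnorm runif sd cor pnorm pt aggregate complete.cases
#' @importFrom methods is
NULL

#' Derive a named substream seed from a master seed
#'
#' All stochastic stages draw from substreams derived deterministically from
#' one master seed, so a single integer reproduces an entire run while stages
#' stay statistically independent.
#'
#' @param seed master integer seed
#' @param name substream name (e.g. "cohort", "density-noise", "ct-noise")
#' @return an integer seed below 2^31
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1999999973
  as.integer((abs(seed) * 2654435761 + h) %% 2147483629)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
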