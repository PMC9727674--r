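#' Clamp values to an interval
#'
#' @param x numeric vector.
#' @param lo,hi interval bounds.
#' @return `x` with values outside `[lo, hi]` replaced by the nearer bound.
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of a study run draws its seed deterministically
#' from the master seed and the stage name, so that re-running a single
#' stage reproduces its output without replaying the whole pipeline.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "bootstrap")
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps seeds in 32-bit range
  h <- as.numeric(master) %% m
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer(h %% (m - 1) + 1)
}

# Accuracy implied by an equal-variance 2AFC observer at (d', c):
# 0.5 * [P(resp = 1 | stim = 1) + P(resp = 0 | stim = 0)].
type1_accuracy <- function(d_prime, criterion = 0) {
  0.5 * (stats::pnorm(d_prime / 2 - criterion) +
           stats::pnorm(d_prime / 2 + criterion))
}
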