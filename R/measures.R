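#' Remap raw 2AFC accuracy to a 0-100 skill/performance score
#'
#' Raw percent correct in a two-alternative forced-choice task ranges from
#' chance (50) to perfect (100). The score subtracts the chance level and
#' multiplies by two, mapping that range onto 0-100. Below-chance input
#' yields a negative score; such participants trip the floor rule upstream.
#'
#' @param raw_pct raw accuracy in percent, in `[0, 100]`.
#' @return the rescaled score `(raw_pct - 50) * 2`.
#' @export
#' @examples
#' remap_accuracy(c(50, 75, 100)) # 0, 50, 100
remap_accuracy <- function(raw_pct) {
  stopifnot(all(raw_pct >= 0 & raw_pct <= 100, na.rm = TRUE))
  (raw_pct - 50) * 2
}

#' Percentile ranks over the full recruited sample
#'
#' Converts performance scores to percentile ranks on a 1-100-compatible
#' scale using the Hazen convention, `100 * (rank - 0.5) / N`, with ties
#' receiving their mean rank. All recruited participants enter the ranking
#' — including those later excluded at floor or ceiling — because the
#' ranking defines the "actual" standing against which relative
#' self-estimates are scored.
#'
#' @param scores numeric performance scores, one per participant (>= 2).
#' @return percentiles in `(0, 100)`, aligned with `scores`.
#' @export
#' @examples
#' percentile_ranks(c(10, 20, 30, 40)) # 12.5 37.5 62.5 87.5
percentile_ranks <- function(scores) {
  stopifnot(length(scores) >= 2L)
  100 * (rank(scores, ties.method = "average") - 0.5) / length(scores)
}

#' Relative and absolute self-estimation errors
#'
#' Relative error subtracts the actual percentile rank from the relative
#' self-estimate; absolute error subtracts the performance score from the
#' absolute self-estimate. Positive values are overestimation.
#'
#' @param relative_estimate self-estimated percentile (1-100).
#' @param absolute_estimate self-estimated score (0-100).
#' @param actual_percentile percentile rank from [percentile_ranks()].
#' @param performance_score remapped test score from [remap_accuracy()].
#' @return `data.frame` with `relative_error` and `absolute_error`.
#' @export
#' @examples
#' estimation_errors(68, 60, 12, 50) # +56 relative, +10 absolute
estimation_errors <- function(relative_estimate, absolute_estimate,
                              actual_percentile, performance_score) {
  data.frame(relative_error = relative_estimate - actual_percentile,
             absolute_error = absolute_estimate - performance_score)
}
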