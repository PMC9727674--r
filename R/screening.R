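#' Floor/ceiling participant screening
#'
#' A participant is excluded from the main analysis when raw accuracy in
#' either phase is at floor (less than or equal to 50\%, i.e. at or below
#' 2AFC chance) or at ceiling (equal to 100\%). The decision is taken
#' *after* percentile ranks have been assigned: every recruited participant,
#' screened out or not, contributes to the ranking that defines relative
#' estimation error.
#'
#' When both phases trigger, the baseline phase is reported first.
#'
#' @param baseline_pct raw baseline accuracy in percent, vector.
#' @param test_pct raw test accuracy in percent, same length.
#' @return `data.frame` with logical `excluded` and character `reason`
#'   (`"baseline_floor"`, `"baseline_ceiling"`, `"test_floor"`,
#'   `"test_ceiling"`, or `NA` when retained).
#' @export
#' @examples
#' screen_floor_ceiling(c(50, 60, 55.8), c(80, 100, 77.5))
screen_floor_ceiling <- function(baseline_pct, test_pct) {
  stopifnot(length(baseline_pct) == length(test_pct),
            all(baseline_pct >= 0 & baseline_pct <= 100, na.rm = TRUE),
            all(test_pct >= 0 & test_pct <= 100, na.rm = TRUE))
  reason <- rep(NA_character_, length(baseline_pct))
  # precedence: baseline before test, floor before ceiling within a phase
  reason[is.na(reason) & baseline_pct <= 50] <- "baseline_floor"
  reason[is.na(reason) & baseline_pct == 100] <- "baseline_ceiling"
  reason[is.na(reason) & test_pct <= 50] <- "test_floor"
  reason[is.na(reason) & test_pct == 100] <- "test_ceiling"
  data.frame(excluded = !is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}

#' Interquartile-range outlier fences
#'
#' Removes values more than `k` interquartile ranges below the first
#' quartile or above the third quartile. Used for the metacognitive
#' efficiency variable, whose ratio construction (meta-d'/d') can explode
#' when d' is near zero; `k = 2` is deliberately conservative. Quartiles use
#' linear interpolation between order statistics (`stats::quantile`
#' type 7), so the fences are exactly reproducible.
#'
#' @param values numeric vector (at least 4 finite values).
#' @param k fence multiplier, default 2.
#' @param ids optional identifiers aligned with `values`.
#' @return list with `retained` (values inside the fences), `removed_ids`,
#'   `keep` (logical mask aligned with input) and the `fences`.
#' @export
iqr_outlier_filter <- function(values, k = 2, ids = seq_along(values)) {
  stopifnot(length(values) >= 4L, length(ids) == length(values))
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE,
                       type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  keep <- !is.na(values) & values >= lo & values <= hi
  list(retained = values[keep], removed_ids = ids[!keep & !is.na(values)],
       keep = keep, fences = c(lower = lo, upper = hi))
}
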