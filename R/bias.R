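#' Metacognitive bias: accuracy-adjusted mean confidence
#'
#' Mean confidence is computed separately for correct and for incorrect
#' responses, and metacognitive bias is the unweighted mean of those two
#' values. Unlike the raw pooled mean, this does not reward high accuracy:
#' a highly accurate rater who is certain when right and uncertain when
#' wrong has a high pooled mean but a mid-scale bias.
#'
#' @param trials test-phase trial rows with `correct` and `confidence`.
#' @return scalar bias in `[1, K]`, or `NA` (with a warning) when either
#'   conditional mean is undefined — such participants have no incorrect
#'   (or no correct) trials and are excluded upstream by the ceiling rule.
#' @export
#' @examples
#' tr <- data.frame(correct = c(TRUE, TRUE, FALSE), confidence = c(4, 2, 1))
#' metacog_bias(tr) # (3 + 1) / 2 = 2
metacog_bias <- function(trials) {
  cm <- confidence_by_accuracy(trials)
  if (is.na(cm["mean_conf_correct"]) || is.na(cm["mean_conf_incorrect"])) {
    warning("metacognitive bias undefined: need both correct and incorrect trials")
    return(NA_real_)
  }
  unname((cm["mean_conf_correct"] + cm["mean_conf_incorrect"]) / 2)
}

#' Mean confidence conditioned on response accuracy
#'
#' @param trials test-phase trial rows with `correct` and `confidence`.
#' @return named numeric vector: `mean_conf_correct`, `mean_conf_incorrect`
#'   (each `NA` when its condition is empty) and `mean_conf_pooled`.
#' @export
confidence_by_accuracy <- function(trials) {
  stopifnot(all(c("correct", "confidence") %in% names(trials)))
  if (nrow(trials) == 0L) stop("no trials")
  conf <- trials$confidence
  ok <- trials$correct
  c(mean_conf_correct = if (any(ok)) mean(conf[ok]) else NA_real_,
    mean_conf_incorrect = if (any(!ok)) mean(conf[!ok]) else NA_real_,
    mean_conf_pooled = mean(conf))
}
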