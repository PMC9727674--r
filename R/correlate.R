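#' Spearman/Pearson correlation with percentile-bootstrap confidence interval
#'
#' Reports both the Spearman rank correlation (the primary statistic of the
#' ranked-data analyses) and the Pearson coefficient, with a nonparametric
#' percentile bootstrap 95\% confidence interval on the requested
#' coefficient, resampling participants (pairs) with replacement. The
#' two-tailed p-value for the requested coefficient uses the t
#' approximation with `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric vectors (complete observations, `n >= 4`).
#' @param method which coefficient the CI and p-value are for.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed for the bootstrap.
#' @param conf_level CI level (default 0.95).
#' @return list of class `"correlation_result"`: `rho`, `r`, `ci_low`,
#'   `ci_high`, `p_value`, `n`, `n_boot`, `n_boot_skipped` (resamples
#'   dropped for zero variance), `method`, `seed`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson"),
                      n_boot = 10000L, seed = 1L, conf_level = 0.95) {
  method <- match.arg(method)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  stopifnot(n >= 4L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in x or y")
  }
  rho <- stats::cor(x, y, method = "spearman")
  r <- stats::cor(x, y, method = "pearson")
  point <- if (method == "spearman") rho else r
  tstat <- point * sqrt((n - 2) / max(1 - point^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  boot <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- x[idx]; yb <- y[idx]
    if (stats::sd(xb) == 0 || stats::sd(yb) == 0) next
    boot[b] <- stats::cor(xb, yb, method = method)
  }
  skipped <- sum(is.na(boot))
  alpha <- (1 - conf_level) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  structure(list(rho = rho, r = r, ci_low = ci[1], ci_high = ci[2],
                 p_value = p, n = n, n_boot = n_boot,
                 n_boot_skipped = skipped, method = method, seed = seed,
                 conf_level = conf_level),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "rho = %.3f, r = %.3f; %s 95%% CI (%.3f, %.3f), p = %.3g, n = %d\n",
    x$rho, x$r, x$method, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' Median split-half reliability of task accuracy
#'
#' For each random split, every participant's trials are divided into two
#' random halves, per-half accuracies are computed, and the Spearman
#' correlation between the two half-accuracies is taken across
#' participants. The reported reliability is the median correlation over
#' splits.
#'
#' @param trials trial `data.frame` with `participant_id` and `correct`
#'   (typically one phase's trials).
#' @param n_splits number of random splits (default 1000).
#' @param seed integer seed.
#' @return list: `reliability` (median Spearman over splits), `splits`
#'   (the per-split correlations), `n_participants`.
#' @export
split_half_reliability <- function(trials, n_splits = 1000L, seed = 1L) {
  ids <- unique(trials$participant_id)
  np <- length(ids)
  stopifnot(np >= 4L)
  by_p <- split(trials$correct, factor(trials$participant_id, levels = ids))
  stopifnot(all(lengths(by_p) >= 2L))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rhos <- vapply(seq_len(n_splits), function(s) {
    acc <- vapply(by_p, function(corr) {
      nt <- length(corr)
      half <- sample.int(nt, nt %/% 2)
      c(mean(corr[half]), mean(corr[-half]))
    }, numeric(2))
    suppressWarnings(stats::cor(acc[1, ], acc[2, ], method = "spearman"))
  }, numeric(1))
  list(reliability = stats::median(rhos, na.rm = TRUE), splits = rhos,
       n_participants = np)
}

#' Fisher-z confidence interval for a correlation
#'
#' Transforms `r` to `atanh(r)`, takes plus/minus the normal quantile times
#' `1/sqrt(n - 3)`, and back-transforms. Used for planning: the expected
#' precision (prediction interval width) of a correlation estimate at a
#' given sample size.
#'
#' @param r correlation, `|r| < 1`.
#' @param n sample size, `n > 3`.
#' @param level confidence level (default 0.95).
#' @return named numeric vector `low`, `high`, `width`.
#' @export
#' @examples
#' round(fisher_ci(0.2, 150), 2) # width 0.31
#' round(fisher_ci(0.8, 150), 2) # width 0.12
fisher_ci <- function(r, n, level = 0.95) {
  stopifnot(abs(r) < 1, n > 3)
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  lo <- tanh(z - half); hi <- tanh(z + half)
  c(low = lo, high = hi, width = hi - lo)
}

#' Power of a correlation test by the Fisher-z normal approximation
#'
#' @param rho true correlation, `0 <= |rho| < 1`.
#' @param n sample size, `n > 3`.
#' @param alpha significance level (default 0.025, i.e. 0.05 adjusted for
#'   two tests).
#' @param sides 1 or 2 (default two-sided).
#' @return the power (at `rho = 0` this equals `alpha`).
#' @export
correlation_power <- function(rho, n, alpha = 0.025, sides = 2) {
  stopifnot(abs(rho) < 1, n > 3, sides %in% c(1, 2))
  zcrit <- stats::qnorm(1 - alpha / sides)
  za <- sqrt(n - 3) * atanh(abs(rho))
  pow <- stats::pnorm(za - zcrit)
  if (sides == 2) pow <- pow + stats::pnorm(-za - zcrit)
  pow
}

#' Smallest sample size reaching a target power
#'
#' Inverts [correlation_power()] by the closed form
#' `n = ceil(((z_crit + z_power) / atanh(rho))^2 + 3)`, then steps to the
#' exact smallest integer `n` whose power clears the target. Conventions
#' differ between power calculators (notably in how the minor tail is
#' handled), so required sizes can differ by a few participants from other
#' software.
#'
#' @inheritParams correlation_power
#' @param power target power.
#' @return smallest integer `n` with `correlation_power(rho, n) >= power`.
#' @export
correlation_required_n <- function(rho, power = 0.99, alpha = 0.025,
                                   sides = 2) {
  stopifnot(abs(rho) > 0, abs(rho) < 1)
  zcrit <- stats::qnorm(1 - alpha / sides)
  n <- ceiling(((zcrit + stats::qnorm(power)) / atanh(abs(rho)))^2 + 3)
  while (n > 4 && correlation_power(rho, n - 1, alpha, sides) >= power) n <- n - 1
  while (correlation_power(rho, n, alpha, sides) < power) n <- n + 1
  as.integer(n)
}
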