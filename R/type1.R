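#' Type-1 signal detection fit from a confidence-count tensor
#'
#' Computes hit and false-alarm rates from the response marginals of a
#' [tally_confidence()] tensor (confidence is ignored at this level) and the
#' equal-variance Gaussian observer parameters
#' \deqn{d' = z(H) - z(FA), \qquad c = -\tfrac{1}{2}\,(z(H) + z(FA)),}
#' where \eqn{z} is the standard normal quantile function, `H` is
#' `P(resp = 1 | stim = 1)` and `FA` is `P(resp = 1 | stim = 0)`.
#'
#' Rates of exactly 0 or 1 make `z` infinite. The maximum-likelihood
#' pipeline applies the conventional 1/(2N) correction (a rate of 0 becomes
#' `1/(2N)`, a rate of 1 becomes `1 - 1/(2N)`, with N the per-class trial
#' count); `correction = "none"` leaves them untouched and returns infinite
#' estimates, which callers must screen. The Bayesian path needs no edge
#' correction and consumes the corrected point estimates only as fixed
#' type-1 anchors.
#'
#' @param counts a `"confidence_counts"` array (or any `2 x 2 x K` count
#'   array, stim by resp by conf).
#' @param correction `"mle"` (default, 1/(2N) edge correction) or `"none"`.
#' @return list of class `"type1_fit"`: `H`, `FA`, `d_prime`, `criterion_c`,
#'   `n_per_class`, `edge_corrected`.
#' @export
fit_type1 <- function(counts, correction = c("mle", "none")) {
  correction <- match.arg(correction)
  stopifnot(length(dim(counts)) == 3L, all(dim(counts)[1:2] == 2L))
  n_stim <- apply(counts, 1, sum)
  if (any(n_stim == 0)) stop("both stimulus classes must be present")
  resp1 <- apply(counts[, 2L, , drop = FALSE], 1, sum)
  FA <- resp1[1] / n_stim[1]
  H <- resp1[2] / n_stim[2]
  edge <- FALSE
  if (correction == "mle") {
    adj <- function(r, n) {
      if (r == 0) r <- 1 / (2 * n) else if (r == 1) r <- 1 - 1 / (2 * n)
      r
    }
    H2 <- adj(H, n_stim[2]); FA2 <- adj(FA, n_stim[1])
    edge <- (H2 != H) || (FA2 != FA)
    H <- H2; FA <- FA2
  }
  zH <- stats::qnorm(H); zFA <- stats::qnorm(FA)
  structure(list(H = unname(H), FA = unname(FA),
                 d_prime = unname(zH - zFA),
                 criterion_c = unname(-0.5 * (zH + zFA)),
                 n_per_class = unname(n_stim), edge_corrected = edge),
            class = "type1_fit")
}

#' @export
print.type1_fit <- function(x, ...) {
  cat(sprintf("type-1 SDT fit: H = %.4f, FA = %.4f, d' = %.4f, c = %.4f%s\n",
              x$H, x$FA, x$d_prime, x$criterion_c,
              if (x$edge_corrected) " (edge corrected)" else ""))
  invisible(x)
}
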