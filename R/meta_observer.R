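#' Construct a type-2 (meta-level) ideal observer
#'
#' The meta observer re-reads the type-1 evidence axis with its own
#' sensitivity `meta_d` (the type-1 d' an SDT-ideal rater would need to
#' produce the observed confidence data). Its decision criterion is the
#' type-1 criterion rescaled to the meta-level axis,
#' \deqn{c' = c \cdot \mathrm{meta\mbox{-}d'} / d',}
#' and `K - 1` response-specific type-2 thresholds on each side of `c'`
#' carve the axis into the K confidence bins: `t2_S1` descends below `c'`
#' (confidence in a class-0 response grows as evidence falls), `t2_S2`
#' ascends above it.
#'
#' @param meta_d meta-level sensitivity (may be negative).
#' @param d_prime,criterion_c the type-1 fit the observer is anchored to;
#'   `d_prime` must be nonzero (the `c'` rescaling is undefined at 0).
#' @param t2_S1 numeric length `K - 1`, thresholds below `c'`, given in
#'   descending order from nearest to farthest from `c'`.
#' @param t2_S2 numeric length `K - 1`, ascending thresholds above `c'`.
#' @return list of class `"meta_observer"` with the fields above plus
#'   `c_prime` and `K`.
#' @seealso [conf_probabilities()], [meta_loglik()], [fit_meta_d_mle()]
#' @export
meta_observer <- function(meta_d, d_prime, criterion_c, t2_S1, t2_S2) {
  if (d_prime == 0) stop("c' is undefined when d' = 0; meta fit must be skipped")
  stopifnot(length(t2_S1) == length(t2_S2))
  c_prime <- criterion_c * meta_d / d_prime
  if (any(diff(t2_S1) > 0)) stop("t2_S1 must be non-increasing (descending below c')")
  if (any(diff(t2_S2) < 0)) stop("t2_S2 must be non-decreasing (ascending above c')")
  if (length(t2_S1) && (t2_S1[1] > c_prime || t2_S2[1] < c_prime)) {
    stop("threshold ordering violated: need t2_S1 <= c' <= t2_S2")
  }
  structure(list(meta_d = meta_d, d_prime = d_prime, criterion_c = criterion_c,
                 c_prime = c_prime, t2_S1 = t2_S1, t2_S2 = t2_S2,
                 K = length(t2_S2) + 1L),
            class = "meta_observer")
}

#' Joint and conditional confidence probabilities of a meta observer
#'
#' For a stimulus class the meta-level evidence is normal with unit variance
#' and mean `-meta_d/2` (class 0) or `+meta_d/2` (class 1). Joint
#' probabilities over (response, confidence) are differences of the normal
#' distribution function over the ordered threshold bins; conditional
#' confidence probabilities divide each response row by that response's
#' probability under the same observer.
#'
#' @param observer a [meta_observer()].
#' @param stim stimulus class, 0 or 1.
#' @return list with `joint` and `conditional`, each a `2 x K` matrix with
#'   rows `resp = 0, 1` and columns confidence 1..K. The joint matrix sums
#'   to 1; each conditional row sums to 1.
#' @export
conf_probabilities <- function(observer, stim) {
  stopifnot(inherits(observer, "meta_observer"), stim %in% c(0, 1))
  mu <- (if (stim == 1) 1 else -1) * observer$meta_d / 2
  p <- meta_cell_probs(observer$c_prime, observer$t2_S1, observer$t2_S2, mu)
  K <- observer$K
  joint <- rbind(`0` = p$joint0, `1` = p$joint1)
  conditional <- rbind(`0` = p$joint0 / p$p_resp0, `1` = p$joint1 / p$p_resp1)
  colnames(joint) <- colnames(conditional) <- as.character(seq_len(K))
  list(joint = joint, conditional = conditional)
}

# bin probabilities for one evidence mean; shared by the R likelihood and
# the simulator. Returns joint rows for resp 0/1 (length K each) and the
# response probabilities they sum to.
meta_cell_probs <- function(c_prime, t2_S1, t2_S2, mu) {
  up <- stats::pnorm(c(c_prime, t2_S2, Inf) - mu)
  joint1 <- diff(up)                               # resp = 1, conf 1..K
  dn <- stats::pnorm(c(c_prime, t2_S1, -Inf) - mu)
  joint0 <- -diff(dn)                              # resp = 0, conf 1..K
  list(joint0 = joint0, joint1 = joint1,
       p_resp0 = dn[1], p_resp1 = 1 - up[1])
}

#' Multinomial log-likelihood of confidence counts under a meta observer
#'
#' The likelihood of the observed ratings is
#' \deqn{L(\theta \mid \mathrm{data}) \propto \prod_{x,i,j}
#'   P_\theta(\mathrm{conf} = x \mid \mathrm{stim} = i, \mathrm{resp} = j)^
#'   {n(\mathrm{conf} = x \mid \mathrm{stim} = i, \mathrm{resp} = j)},}
#' i.e. a product of conditional confidence probabilities, one factor per
#' trial. Cells with zero count contribute 0; a zero-probability cell with a
#' positive count yields `-Inf` (returned, not raised).
#'
#' @param counts a `"confidence_counts"` tensor.
#' @param observer a [meta_observer()].
#' @return the log-likelihood (scalar, possibly `-Inf`).
#' @export
meta_loglik <- function(counts, observer) {
  stopifnot(length(dim(counts)) == 3L)
  K <- dim(counts)[3]
  stopifnot(K == observer$K)
  ll <- 0
  for (stim in 0:1) {
    cond <- conf_probabilities(observer, stim)$conditional
    n <- rbind(counts[stim + 1L, 1L, ], counts[stim + 1L, 2L, ])
    pos <- n > 0
    if (!any(pos)) next
    ll <- ll + sum(n[pos] * log(cond[pos]))
  }
  ll
}
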