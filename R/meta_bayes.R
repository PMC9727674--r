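# JAGS model for single-participant, non-response-conditional meta-d'
# estimation with the type-1 parameters (d', c) held fixed. The prior on
# meta-d' is Normal(d', variance 2); type-2 thresholds are built from
# log-increments away from c' with wide Normal(0, sd 2) priors, which keeps
# the ordering invariant by construction. Confidence counts within each
# observed (stim, resp) cell are multinomial in the conditional
# probabilities, exactly the likelihood maximised by the MLE path.
meta_d_jags_model <- "
model {
  meta_d ~ dnorm(d1, 0.5)
  c_prime <- cc * meta_d / d1
  for (k in 1:(K - 1)) {
    lS2[k] ~ dnorm(0, 0.25)
    lS1[k] ~ dnorm(0, 0.25)
  }
  tau_S2[1] <- c_prime + exp(lS2[1])
  tau_S1[1] <- c_prime - exp(lS1[1])
  for (k in 2:(K - 1)) {
    tau_S2[k] <- tau_S2[k - 1] + exp(lS2[k])
    tau_S1[k] <- tau_S1[k - 1] - exp(lS1[k])
  }
  mu[1] <- -meta_d / 2
  mu[2] <-  meta_d / 2
  for (i in 1:2) {
    edge_up[i, 1] <- phi(c_prime - mu[i])
    edge_dn[i, 1] <- phi(c_prime - mu[i])
    for (k in 1:(K - 1)) {
      edge_up[i, k + 1] <- phi(tau_S2[k] - mu[i])
      edge_dn[i, k + 1] <- phi(tau_S1[k] - mu[i])
    }
    for (k in 1:(K - 1)) {
      joint1[i, k] <- edge_up[i, k + 1] - edge_up[i, k]
      joint0[i, k] <- edge_dn[i, k] - edge_dn[i, k + 1]
    }
    joint1[i, K] <- 1 - edge_up[i, K]
    joint0[i, K] <- edge_dn[i, K]
    for (k in 1:K) {
      # tiny floor keeps the normalised multinomial weights valid when a
      # bin probability underflows
      pc[i, 1, k] <- max(joint0[i, k] / max(edge_dn[i, 1], 1e-12), 1e-12)
      pc[i, 2, k] <- max(joint1[i, k] / max(1 - edge_up[i, 1], 1e-12), 1e-12)
    }
  }
  for (r in 1:nrows) {
    y[r, 1:K] ~ dmulti(pc[si[r], ri[r], 1:K], sz[r])
  }
}
"

#' Bayesian meta-d' fit by single-participant MCMC
#'
#' Samples the posterior of meta-d' (and the type-2 thresholds) with the
#' type-1 parameters fixed at their point estimates. The prior on meta-d'
#' is a normal distribution with mean equal to the observed d' and
#' variance 2; sampling runs three chains of 10 000 retained samples each
#' after a 1 000-sample burn-in (all configurable). Convergence is
#' summarised by the Gelman-Rubin statistic per monitored parameter; a fit
#' with R-hat above `rhat_threshold` is flagged `non_converged` but still
#' returned.
#'
#' Metacognitive efficiency is the mean over posterior samples of the ratio
#' meta-d'/d' with d' fixed, which equals the posterior mean of meta-d'
#' divided by d'.
#'
#' With an all-zero count tensor the likelihood is flat and the posterior
#' equals the prior; this case is sampled directly from the prior.
#'
#' @param counts a [tally_confidence()] tensor.
#' @param type1 a [fit_type1()] result with nonzero `d_prime`.
#' @param chains,samples,burn_in MCMC settings (defaults 3, 10000, 1000).
#' @param seed integer seed; chains use consecutive derived seeds, so the
#'   same seed reproduces the samples exactly.
#' @param rhat_threshold flag threshold for the convergence diagnostic.
#' @return list of class `"meta_fit"`: `meta_d_hat` (posterior mean),
#'   `efficiency`, `posterior_samples` (vector, all chains pooled),
#'   `chain_sample_counts`, `diagnostics` (R-hat per parameter),
#'   `non_converged`, `method = "bayes"`, `seed`.
#' @export
fit_meta_d_bayes <- function(counts, type1, chains = 3L, samples = 10000L,
                             burn_in = 1000L, seed = 1L,
                             rhat_threshold = 1.05) {
  stopifnot(inherits(type1, "type1_fit"))
  if (type1$d_prime == 0) stop("meta fit is undefined at d' = 0")
  K <- dim(counts)[3]

  if (sum(counts) == 0) {
    # flat likelihood: posterior == prior
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    draws <- matrix(stats::rnorm(chains * samples, mean = type1$d_prime,
                                 sd = sqrt(2)), ncol = chains)
    post <- as.vector(draws)
    return(structure(list(
      meta_d_hat = mean(post), efficiency = mean(post / type1$d_prime),
      posterior_samples = post,
      chain_sample_counts = rep(samples, chains),
      diagnostics = c(meta_d = 1), non_converged = FALSE,
      method = "bayes", seed = seed, prior_only = TRUE),
      class = "meta_fit"))
  }

  # one multinomial row per non-empty (stim, resp) cell
  rows <- which(apply(counts, c(1, 2), sum) > 0, arr.ind = TRUE)
  y <- t(apply(rows, 1, function(idx) counts[idx[1], idx[2], ]))
  data <- list(y = y, sz = rowSums(y), si = rows[, 1], ri = rows[, 2],
               nrows = nrow(rows), K = K,
               d1 = type1$d_prime, cc = type1$criterion_c)
  inits <- lapply(seq_len(chains), function(ch) {
    list(meta_d = type1$d_prime, lS2 = rep(log(0.5), K - 1),
         lS1 = rep(log(0.5), K - 1),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(seed, paste0("chain", ch)))
  })
  model <- rjags::jags.model(textConnection(meta_d_jags_model), data = data,
                             inits = inits, n.chains = chains, n.adapt = 500,
                             quiet = TRUE)
  stats::update(model, n.iter = burn_in, progress.bar = "none")
  mcmc <- rjags::coda.samples(model, variable.names = c("meta_d"),
                              n.iter = samples, progress.bar = "none")
  rhat <- tryCatch(
    coda::gelman.diag(mcmc, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1],
    error = function(e) NA_real_)
  names(rhat) <- "meta_d"
  post <- as.vector(unlist(lapply(mcmc, function(ch) as.vector(ch[, "meta_d"]))))
  structure(list(
    meta_d_hat = mean(post),
    efficiency = mean(post / type1$d_prime),
    posterior_samples = post,
    chain_sample_counts = vapply(mcmc, nrow, integer(1)),
    diagnostics = rhat,
    non_converged = is.na(rhat["meta_d"]) || rhat["meta_d"] > rhat_threshold,
    method = "bayes", seed = seed, prior_only = FALSE),
    class = "meta_fit")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
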