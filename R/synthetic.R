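#' Configuration of a synthetic study cohort
#'
#' Describes the generative model the analysis pipeline assumes: a cohort
#' with heterogeneous latent skill doing a two-alternative forced-choice
#' task (48 baseline trials, then 90 test trials with 4-level confidence
#' ratings and a practice benefit between phases), followed by two noisy,
#' regressive global self-estimates.
#'
#' Latent skill is a truncated-normal d' (mean 1.0, sd 0.6, floor 0, which
#' puts typical baseline accuracy in the 55-85\% band). The test phase runs
#' at `d' + practice_gain`. Confidence comes from a type-2 observer at
#' `meta-d' = efficiency_profile(d') * d'_test`; the default profile is the
#' constant 0.8, i.e. metacognition reads 80\% of the first-order signal at
#' every skill level — a cohort with *no* metacognitive deficit by
#' construction. Self-estimates are a weighted pull `w` toward the truth
#' with the remainder anchored at a configurable default (optimistic, 58,
#' for the relative percentile; mid-scale, 62, for the absolute score —
#' pessimistic relative to typical performance) plus Gaussian noise.
#'
#' @param n_participants cohort size (default 150).
#' @param n_baseline_trials,n_test_trials trials per phase (48, 90).
#' @param skill_mean,skill_sd,skill_floor truncated-normal latent d'.
#' @param practice_gain additive d' increment from baseline to test (0.5).
#' @param efficiency_profile function mapping latent d' to meta-d'/d' in
#'   `[0, 1.2]`.
#' @param criterion type-1 criterion c (0 = unbiased).
#' @param conf_offsets `K - 1` ascending positive offsets placing the
#'   type-2 thresholds symmetrically around the meta-level criterion.
#' @param K confidence levels (4).
#' @param confidence_generator `"multinomial"` (sample ratings from the
#'   meta-observer conditional distribution — the generative model is then
#'   exactly the fitted model) or `"evidence"` (bin a noisy copy of the
#'   same evidence sample that produced the response; `meta_noise_sd`
#'   controls the degradation, 0 = ideal observer).
#' @param meta_noise_sd evidence-route meta-level noise sd.
#' @param est_weight weight `w` on truth in the self-estimates (0.3).
#' @param anchor_relative,anchor_absolute regression anchors (58, 62).
#' @param est_noise_sd self-estimate noise sd (15).
#' @param seed master seed for the cohort.
#' @return list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_participants = 150L,
                          n_baseline_trials = 48L, n_test_trials = 90L,
                          skill_mean = 1.0, skill_sd = 0.6, skill_floor = 0,
                          practice_gain = 0.5,
                          efficiency_profile = function(d) rep(0.8, length(d)),
                          criterion = 0,
                          conf_offsets = c(0.5, 1.0, 1.5), K = 4L,
                          confidence_generator = c("multinomial", "evidence"),
                          meta_noise_sd = 0,
                          est_weight = 0.3,
                          anchor_relative = 58, anchor_absolute = 62,
                          est_noise_sd = 15, seed = 1L) {
  confidence_generator <- match.arg(confidence_generator)
  stopifnot(n_participants >= 1, n_baseline_trials >= 1, n_test_trials >= 1,
            skill_sd >= 0, length(conf_offsets) == K - 1L,
            all(diff(conf_offsets) > 0), all(conf_offsets > 0),
            est_weight >= 0, est_weight <= 1, est_noise_sd >= 0,
            anchor_relative >= 1, anchor_relative <= 100,
            anchor_absolute >= 0, anchor_absolute <= 100)
  eff <- efficiency_profile(seq(0, 4, by = 0.5))
  stopifnot(all(eff >= 0), all(eff <= 1.2))
  structure(as.list(environment()), class = "cohort_config")
}

# 2AFC type-1 trials at (d', c): stimulus class is equiprobable, evidence is
# unit normal around -d'/2 (class 0) or +d'/2 (class 1), response is the
# evidence sign relative to c. Returns evidence too (the evidence-route
# confidence generator reuses it).
simulate_type1_trials <- function(n, d_prime, criterion) {
  stim <- stats::rbinom(n, 1L, 0.5)
  x <- stats::rnorm(n, mean = (2 * stim - 1) * d_prime / 2, sd = 1)
  resp <- as.integer(x > criterion)
  data.frame(stim = stim, resp = resp, correct = stim == resp, evidence = x)
}

#' Simulate 2AFC trials with confidence from the same evidence sample
#'
#' The evidence-route generator: the rating is a binned read-out of the
#' very evidence sample that produced the type-1 response, optionally
#' degraded by independent meta-level noise before binning. With
#' `meta_noise_sd = 0` this is the metacognitively ideal observer, for
#' which fitted meta-d' converges to d'; increasing the noise strictly
#' degrades the expected fitted meta-d'.
#'
#' @param n number of trials.
#' @param d_prime,criterion type-1 observer parameters.
#' @param conf_offsets ascending positive threshold offsets (length K-1).
#' @param meta_noise_sd sd of noise added to the evidence before binning.
#' @param seed optional integer seed.
#' @return trial `data.frame` with `stim`, `resp`, `correct`, `confidence`.
#' @export
simulate_evidence_trials <- function(n, d_prime, criterion = 0,
                                     conf_offsets = c(0.5, 1.0, 1.5),
                                     meta_noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  tr <- simulate_type1_trials(n, d_prime, criterion)
  y <- tr$evidence + stats::rnorm(n, 0, meta_noise_sd)
  z <- ifelse(tr$resp == 1L, y - criterion, criterion - y)
  tr$confidence <- 1L + as.integer(rowSums(outer(z, conf_offsets, `>`)))
  tr$evidence <- NULL
  tr
}

# multinomial-route confidence: sample ratings from the meta-observer
# conditional distribution P(conf | stim, resp) at the given meta-d'.
sample_conf_multinomial <- function(tr, meta_d, d_prime, criterion,
                                    conf_offsets, K) {
  c_prime <- if (d_prime == 0) criterion else criterion * meta_d / d_prime
  t2_S1 <- c_prime - conf_offsets
  t2_S2 <- c_prime + conf_offsets
  conf <- integer(nrow(tr))
  for (s in 0:1) {
    mu <- (if (s == 1) 1 else -1) * meta_d / 2
    p <- meta_cell_probs(c_prime, t2_S1, t2_S2, mu)
    for (r in 0:1) {
      sel <- tr$stim == s & tr$resp == r
      if (!any(sel)) next
      pr <- if (r == 1) p$joint1 / p$p_resp1 else p$joint0 / p$p_resp0
      conf[sel] <- sample.int(K, sum(sel), replace = TRUE, prob = pr)
    }
  }
  conf
}

#' Simulate one participant
#'
#' Baseline trials run the type-1 observer at the latent d'; test trials
#' run at `d' + practice_gain` and add confidence ratings at
#' `meta-d' = efficiency_profile(d') * d'_test`. The relative self-estimate
#' is `clamp(w * true_percentile + (1 - w) * anchor + noise, 1, 100)`; the
#' absolute estimate is the analogue on the 0-100 score scale, anchored on
#' the closed-form expected performance score.
#'
#' @param config a [cohort_config()].
#' @param participant_id id string.
#' @param latent_d latent skill d'.
#' @param true_percentile the participant's true standing (1-100) in the
#'   cohort; within [simulate_cohort()] it is the Hazen percentile of the
#'   latent d' rank.
#' @param seed participant-level seed.
#' @param n_test_override optional test-trial count (large-trial recovery
#'   checks).
#' @return list: `trials` (both phases, standard columns), `estimates`
#'   (one-row `data.frame`), `truth` (latent parameters).
#' @export
simulate_participant <- function(config, participant_id, latent_d,
                                 true_percentile, seed,
                                 n_test_override = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_test <- if (is.null(n_test_override)) config$n_test_trials else n_test_override

  base <- simulate_type1_trials(config$n_baseline_trials, latent_d,
                                config$criterion)
  d_test <- latent_d + config$practice_gain
  eff <- config$efficiency_profile(latent_d)
  meta_d <- eff * d_test
  test <- simulate_type1_trials(n_test, d_test, config$criterion)
  if (config$confidence_generator == "multinomial") {
    test$confidence <- sample_conf_multinomial(
      test, meta_d, d_test, config$criterion, config$conf_offsets, config$K)
  } else {
    y <- test$evidence + stats::rnorm(n_test, 0, config$meta_noise_sd)
    z <- ifelse(test$resp == 1L, y - config$criterion, config$criterion - y)
    test$confidence <- 1L +
      as.integer(rowSums(outer(z, config$conf_offsets, `>`)))
  }
  base$evidence <- test$evidence <- NULL
  base$confidence <- NA_integer_

  trials <- rbind(
    data.frame(participant_id = participant_id, phase = "baseline",
               trial_index = seq_len(nrow(base)), base,
               stringsAsFactors = FALSE),
    data.frame(participant_id = participant_id, phase = "test",
               trial_index = seq_len(nrow(test)), test,
               stringsAsFactors = FALSE))

  expected_score <- remap_accuracy(100 * type1_accuracy(d_test, config$criterion))
  w <- config$est_weight
  rel <- clamp(w * true_percentile + (1 - w) * config$anchor_relative +
                 stats::rnorm(1, 0, config$est_noise_sd), 1, 100)
  abs_est <- clamp(w * expected_score + (1 - w) * config$anchor_absolute +
                     stats::rnorm(1, 0, config$est_noise_sd), 0, 100)
  estimates <- data.frame(participant_id = participant_id,
                          relative_estimate = rel, absolute_estimate = abs_est,
                          stringsAsFactors = FALSE)
  truth <- data.frame(participant_id = participant_id, latent_d = latent_d,
                      d_test = d_test, meta_d = meta_d, efficiency = eff,
                      true_percentile = true_percentile,
                      expected_score = expected_score, seed = seed,
                      stringsAsFactors = FALSE)
  list(trials = trials, estimates = estimates, truth = truth)
}

#' Simulate a full study cohort
#'
#' Draws latent skills, assigns true percentiles from the latent-skill
#' ranks, and simulates every participant independently with a seed
#' derived from the cohort seed, so the same configuration reproduces the
#' cohort bit for bit.
#'
#' @param config a [cohort_config()].
#' @return list of class `"cohort"`: `trials`, `estimates`, `truth`
#'   (`data.frame`s in the standard formats), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, "skills"))
  n <- config$n_participants
  lo <- stats::pnorm((config$skill_floor - config$skill_mean) /
                       max(config$skill_sd, .Machine$double.eps))
  u <- stats::runif(n, lo, 1)
  latent <- config$skill_mean + config$skill_sd * stats::qnorm(u)
  if (config$skill_sd == 0) latent <- rep(max(config$skill_mean,
                                              config$skill_floor), n)
  pct <- if (n >= 2) percentile_ranks(latent) else 50
  ids <- sprintf("P%03d", seq_len(n))
  parts <- lapply(seq_len(n), function(i) {
    simulate_participant(config, ids[i], latent[i], pct[i],
                         seed = derive_seed(config$seed, paste0("p-", i)))
  })
  structure(list(
    trials = do.call(rbind, lapply(parts, `[[`, "trials")),
    estimates = do.call(rbind, lapply(parts, `[[`, "estimates")),
    truth = do.call(rbind, lapply(parts, `[[`, "truth")),
    config = config), class = "cohort")
}
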