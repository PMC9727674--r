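test_that("the same seed reproduces a cohort bit for bit", {
  cfg <- cohort_config(n_participants = 6, seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$estimates, c2$estimates)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_cohort(cohort_config(n_participants = 6, seed = 78))
  expect_false(identical(c1$trials, c3$trials))
})

test_that("cohort dimensions are conserved", {
  cfg <- cohort_config(n_participants = 12, seed = 5)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$trials), 12 * (48 + 90))
  expect_equal(nrow(coh$estimates), 12)
  expect_equal(nrow(coh$truth), 12)
  expect_true(all(table(coh$trials$phase) == c(12 * 48, 12 * 90)))
  # baseline rows carry no confidence; test rows always do
  expect_true(all(is.na(coh$trials$confidence[coh$trials$phase == "baseline"])))
  expect_true(all(!is.na(coh$trials$confidence[coh$trials$phase == "test"])))
  # the emitted tables round-trip through the standard reader
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_trials(coh$trials, p1)
  write.table(coh$estimates, p2, sep = ",", row.names = FALSE, quote = FALSE)
  td <- read_trials(p1, p2)
  expect_equal(nrow(td$rejected), 0L)
  expect_equal(nrow(td$trials), nrow(coh$trials))
})

test_that("generated accuracy matches the closed-form observer accuracy", {
  cfg <- cohort_config(n_participants = 1, practice_gain = 0.5,
                       criterion = 0.2, seed = 9)
  pp <- simulate_participant(cfg, "X", latent_d = 1.1, true_percentile = 50,
                             seed = 14, n_test_override = 4e4)
  tt <- pp$trials[pp$trials$phase == "test", ]
  p_expected <- metadke:::type1_accuracy(1.6, 0.2)
  p_hat <- mean(tt$correct)
  se <- sqrt(p_expected * (1 - p_expected) / nrow(tt))
  expect_lt(abs(p_hat - p_expected), 4 * se)
})

test_that("confidence tallies match the meta-observer cell probabilities", {
  # chi-square goodness of fit per (stim, resp) cell at 1e4 trials
  cfg <- cohort_config(n_participants = 1, seed = 2)
  rejected <- 0L; total <- 0L
  for (s in 1:8) {
    d <- runif(1, 0.6, 2)
    pp <- simulate_participant(cfg, "X", d, 50, seed = 400 + s,
                               n_test_override = 1e4)
    tt <- pp$trials[pp$trials$phase == "test", ]
    d_t <- d + 0.5; m <- 0.8 * d_t
    cp <- 0 # criterion 0 so c' = 0
    for (stim in 0:1) {
      mu <- (if (stim == 1) 1 else -1) * m / 2
      pr <- metadke:::meta_cell_probs(cp, cp - c(0.5, 1, 1.5),
                                      cp + c(0.5, 1, 1.5), mu)
      for (r in 0:1) {
        sel <- tt$stim == stim & tt$resp == r
        if (sum(sel) < 50) next
        obs <- tabulate(tt$confidence[sel], nbins = 4)
        prob <- if (r == 1) pr$joint1 / pr$p_resp1 else pr$joint0 / pr$p_resp0
        pval <- suppressWarnings(chisq.test(obs, p = prob)$p.value)
        total <- total + 1L
        if (pval < 0.01) rejected <- rejected + 1L
      }
    }
  }
  expect_lte(rejected / total, 0.05)
})

test_that("pipeline efficiency estimates track true efficiency (slope ~ 1)", {
  cfg <- cohort_config(n_participants = 1,
                       efficiency_profile = function(d)
                         pmin(pmax(0.45 + 0.25 * d, 0.2), 1.1),
                       seed = 4)
  n_p <- 60
  set.seed(60)
  lat <- runif(n_p, 0.5, 2)
  res <- t(sapply(seq_len(n_p), function(i) {
    pp <- simulate_participant(cfg, "X", lat[i], 50, seed = 600 + i,
                               n_test_override = 2000)
    tt <- pp$trials[pp$trials$phase == "test", ]
    cnt <- tally_confidence(tt)
    t1 <- fit_type1(cnt)
    c(true = pp$truth$efficiency, est = fit_meta_d_mle(cnt, t1)$efficiency)
  }))
  slope <- coef(lm(res[, "est"] ~ res[, "true"]))[2]
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("no skill variance means no reliability; realistic variance means rank stability", {
  flat <- simulate_cohort(cohort_config(n_participants = 40, skill_sd = 0,
                                        seed = 11))
  s_flat <- split_half_reliability(
    flat$trials[flat$trials$phase == "test", ], n_splits = 150, seed = 1)
  expect_lt(abs(s_flat$reliability), 0.2)

  coh <- simulate_cohort(cohort_config(n_participants = 100, seed = 12))
  base_acc <- tapply(coh$trials$correct[coh$trials$phase == "baseline"],
                     coh$trials$participant_id[coh$trials$phase == "baseline"],
                     mean)
  test_acc <- tapply(coh$trials$correct[coh$trials$phase == "test"],
                     coh$trials$participant_id[coh$trials$phase == "test"],
                     mean)
  expect_gt(cor(base_acc, test_acc, method = "spearman"), 0.6)
})

test_that("perfect self-knowledge leaves only rank-measurement noise in errors", {
  cfg <- cohort_config(n_participants = 60, est_weight = 1, est_noise_sd = 0,
                       seed = 13)
  coh <- simulate_cohort(cfg)
  s <- participant_summaries(coh$trials, coh$estimates)
  ok <- !s$excluded
  expect_lt(abs(mean(s$relative_error[ok])), 6)
  expect_lt(abs(mean(s$absolute_error[ok])), 6)
  # with anchored, noisy estimates the same cohort shows large spread
  cfg2 <- cohort_config(n_participants = 60, seed = 13)
  s2 <- participant_summaries(simulate_cohort(cfg2)$trials,
                              simulate_cohort(cfg2)$estimates)
  expect_gt(sd(s2$relative_error[!s2$excluded]),
            sd(s$relative_error[ok]))
})

test_that("a pessimistic absolute anchor flips the over/underestimation asymmetry", {
  cfg <- cohort_config(n_participants = 120, anchor_absolute = 20, seed = 17)
  coh <- simulate_cohort(cfg)
  s <- participant_summaries(coh$trials, coh$estimates)
  s <- s[!s$excluded, ]
  top <- s$cognitive_skill >= quantile(s$cognitive_skill, 0.75)
  bottom <- s$cognitive_skill <= quantile(s$cognitive_skill, 0.25)
  under_top <- -mean(s$absolute_error[top])      # underestimation at the top
  over_bottom <- mean(s$absolute_error[bottom])  # overestimation at the bottom
  expect_gt(under_top, 0)
  expect_gt(under_top, over_bottom)
})

test_that("with constant true efficiency the efficiency-d' association is only
           the ratio artifact, and it fades with trial count", {
  # meta-d'/d' shares its denominator with d-hat, so estimation noise induces
  # a small negative association even though no true relation exists; the
  # artifact must shrink as trial noise shrinks
  rho_at <- function(nt, seeds) {
    vapply(seeds, function(s) {
      coh <- simulate_cohort(cohort_config(n_participants = 80,
                                           n_test_trials = nt, seed = s))
      su <- participant_summaries(coh$trials, coh$estimates)
      use <- su[!su$excluded, ]
      cor(use$d_prime, use$efficiency, method = "spearman")
    }, numeric(1))
  }
  rho_90 <- rho_at(90, 5001:5006)
  expect_gt(mean(rho_90), -0.4)  # artifact stays modest at study scale
  expect_lt(mean(rho_90), 0.15)  # and there is certainly no positive relation
  # at 1000 trials/participant the bootstrap CI typically covers zero
  covers <- vapply(6001:6004, function(s) {
    coh <- simulate_cohort(cohort_config(n_participants = 80,
                                         n_test_trials = 1000, seed = s))
    su <- participant_summaries(coh$trials, coh$estimates)
    use <- su[!su$excluded, ]
    cr <- correlate(use$d_prime, use$efficiency, n_boot = 400, seed = s)
    cr$ci_low <= 0 && cr$ci_high >= 0
  }, logical(1))
  expect_gte(sum(covers), 3L)
})
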