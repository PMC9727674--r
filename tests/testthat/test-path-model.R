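test_that("rank_transform is invariant to monotone maps and matches its oracle", {
  set.seed(8)
  x <- rnorm(40); y <- runif(40)
  dat <- cbind(a = x, b = y)
  rt <- rank_transform(dat)
  expect_equal(rank_transform(cbind(a = exp(x), b = y^3)), rt)
  expect_equal(rank_transform(cbind(a = -x, b = y))[, "a"], -rt[, "a"])
  # independent rank-then-zscore oracle
  oracle <- scale(apply(dat, 2, rank))
  expect_equal(rt, oracle, ignore_attr = TRUE)
  expect_error(rank_transform(cbind(a = rep(1, 10), b = y[1:10])), "constant")
})

test_that("indirect effects recover generative truth through one mediator", {
  dat <- simulate_path_data(1e4, a = c(0.8, 0, 0, 0), b = c(-0.7, 0, 0, 0),
                            seed = 101)
  fit <- fit_path_model(dat, path_model(), n_boot = 400, seed = 1)
  ind <- fit$paths$estimate[match(paste0("indirect_", c("PERFORM", "M_SENSE",
                                                        "M_EFFIC", "M_BIAS")),
                                  fit$paths$path)]
  expect_equal(ind[1], -0.56, tolerance = 0.03)
  expect_true(all(abs(ind[2:4]) < 0.03))
  expect_equal(fit$total_effect, -0.56, tolerance = 0.03)
})

test_that("independent variables yield null paths with CIs covering zero", {
  set.seed(55)
  dat <- matrix(rnorm(6 * 400), ncol = 6,
                dimnames = list(NULL, c("SKILL", "PERFORM", "M_SENSE",
                                        "M_EFFIC", "M_BIAS", "EST_ERR")))
  fit <- fit_path_model(dat, path_model(), n_boot = 400, seed = 2)
  ab <- fit$paths[grepl("^[ab]_", fit$paths$path), ]
  expect_true(all(abs(ab$estimate) < 0.15))
  expect_true(mean(ab$ci_low <= 0 & ab$ci_high >= 0) >= 0.75)
})

test_that("structural identities hold on any fit", {
  dat <- simulate_path_data(500, a = c(0.6, 0.4, 0.2, 0.3),
                            b = c(-0.5, 0.2, 0.1, -0.1), seed = 7)
  fit <- fit_path_model(dat, path_model(), n_boot = 100, seed = 3)
  inds <- fit$paths$estimate[grepl("^indirect_", fit$paths$path)]
  expect_equal(fit$total_effect, sum(inds), tolerance = 1e-10)
  expect_equal(fit$AIC, -2 * fit$loglik + 2 * fit$k_params, tolerance = 1e-10)
  expect_equal(fit$df, 1)
  mc <- fit$paths$estimate[grepl("^indirect_M_", fit$paths$path)]
  expect_equal(fit$total_metacognition, sum(mc), tolerance = 1e-12)
})

test_that("a null mediator is dropped first; strong models are not reduced", {
  dat <- simulate_path_data(800, a = c(0.7, 0.5, 0, 0.4),
                            b = c(-0.6, 0.25, 0, 0.2), seed = 21)
  red <- reduce_model(dat, n_boot = 300, seed = 5)
  expect_equal(red$trace$action[2], "dropped M_EFFIC")

  strong <- simulate_path_data(2000, a = c(0.7, 0.5, 0.45, 0.4),
                               b = c(-0.6, 0.3, 0.25, 0.2), seed = 22)
  red2 <- reduce_model(strong, n_boot = 300, seed = 6)
  expect_equal(red2$selected$model$mediators,
               c("PERFORM", "M_SENSE", "M_EFFIC", "M_BIAS"))
})

test_that("model reduction is deterministic, including its tie-break path", {
  dat <- simulate_path_data(600, a = c(0.7, 0.5, 0.1, 0.1),
                            b = c(-0.6, 0.25, 0.02, 0.02), seed = 31)
  r1 <- reduce_model(dat, n_boot = 300, seed = 7)
  r2 <- reduce_model(dat, n_boot = 300, seed = 7)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$selected$paths, r2$selected$paths)
  # the trace records every decision, ending in the selected model
  expect_equal(r1$trace$model[nrow(r1$trace)],
               paste(r1$selected$model$mediators, collapse = "+"))
})

test_that("model comparison arithmetic follows exp(delta AIC / 2)", {
  expect_equal(round(compare_models(2, 0)$relative_likelihood, 2), 2.72)
  expect_equal(compare_models(10, 10)$relative_likelihood, 1.0)
  expect_equal(compare_models(10, 10)$preferred, "tie")
  cmp <- compare_models(5633, 2748)
  expect_equal(cmp$delta_aic, 2885)
  expect_equal(cmp$preferred, "b")
  expect_true(cmp$capped) # e^1442.5 overflows; sentinel documented
  expect_equal(compare_models(4291, 2858)$delta_aic, 1433)
})

test_that("the performance-only model is the single-path special case", {
  dat <- simulate_path_data(1e4, a = c(0.8, 0, 0, 0), b = c(-0.7, 0, 0, 0),
                            seed = 41)
  po <- performance_only_model(dat, n_boot = 300, seed = 8)
  expect_equal(po$total_effect, -0.56, tolerance = 0.03)
  expect_equal(po$total_effect,
               po$paths$estimate[po$paths$path == "indirect_PERFORM"],
               tolerance = 1e-12)
  full <- fit_path_model(dat, path_model(), n_boot = 100, seed = 9)
  expect_lt(po$k_params, full$k_params)
  expect_equal(po$total_metacognition, 0)
})

test_that("path estimates are unbiased at study-sized samples", {
  # CI calibration over many replicates is exercised by the acceptance
  # suite; here only the point-estimate bias
  a_true <- c(0.7, 0.5, 0.3, 0.4)
  b_true <- c(-0.55, 0.2, 0.05, 0.1)
  reps <- 80
  est <- matrix(NA_real_, reps, 8)
  set.seed(91)
  for (r in seq_len(reps)) {
    dat <- simulate_path_data(150, a_true, b_true)
    fit <- fit_path_model(dat, path_model(), n_boot = 50, seed = r)
    est[r, ] <- fit$paths$estimate[grepl("^[ab]_", fit$paths$path)]
  }
  bias <- abs(colMeans(est) - c(a_true, b_true))
  expect_true(all(bias < 0.06))
})
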