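test_that("perfect monotone association gives rho = +/-1", {
  x <- c(1, 3, 4, 7, 10)
  up <- correlate(x, exp(x), n_boot = 50, seed = 1)
  expect_equal(up$rho, 1)
  dn <- correlate(x, -x^3, n_boot = 50, seed = 1)
  expect_equal(dn$rho, -1)
})

test_that("independent pairs give near-zero rho with a CI covering zero", {
  covered <- 0L
  for (r in 1:10) {
    set.seed(100 + r)
    x <- rnorm(1000); y <- rnorm(1000)
    cr <- correlate(x, y, n_boot = 300, seed = r)
    expect_lt(abs(cr$rho), 0.08)
    if (cr$ci_low <= 0 && cr$ci_high >= 0) covered <- covered + 1L
  }
  expect_gte(covered, 9L)
})

test_that("zero variance is refused", {
  expect_error(correlate(rep(1, 10), rnorm(10), n_boot = 10), "zero variance")
})

test_that("bootstrap CI calibration: ~95% coverage for bivariate normal data", {
  rho_true <- 0.5
  n <- 150; reps <- 200
  covered <- 0L
  set.seed(2024)
  for (r in seq_len(reps)) {
    x <- rnorm(n)
    y <- rho_true * x + sqrt(1 - rho_true^2) * rnorm(n)
    cr <- correlate(x, y, method = "pearson", n_boot = 400, seed = r)
    if (cr$ci_low <= rho_true && cr$ci_high >= rho_true) covered <- covered + 1L
  }
  expect_gte(covered / reps, 0.92)
  expect_lte(covered / reps, 0.98)
})

test_that("Fisher-z planning intervals reproduce the published widths", {
  ci02 <- fisher_ci(0.2, 150)
  expect_equal(unname(round(ci02["width"], 2)), 0.31)
  expect_equal(unname(round(ci02[c("low", "high")], 2)), c(0.04, 0.35))
  ci08 <- fisher_ci(0.8, 150)
  expect_equal(unname(round(ci08["width"], 2)), 0.12)
  expect_equal(unname(round(ci08[c("low", "high")], 2)), c(0.73, 0.85))
  # symmetric about zero at r = 0
  ci0 <- fisher_ci(0, 80)
  expect_equal(unname(ci0["low"]), -unname(ci0["high"]))
})

test_that("fisher_ci width shrinks with |r| and with n", {
  widths_r <- sapply(c(0, 0.2, 0.4, 0.6, 0.8), function(r)
    fisher_ci(r, 150)["width"])
  expect_true(all(diff(widths_r) < 0))
  widths_n <- sapply(c(20, 50, 150, 500), function(n)
    fisher_ci(0.3, n)["width"])
  expect_true(all(diff(widths_n) < 0))
})

test_that("correlation power behaves like the closed form", {
  expect_equal(correlation_power(1e-12, 200), 0.025, tolerance = 1e-6)
  pow <- sapply(c(50, 100, 200, 400), function(n) correlation_power(0.3, n))
  expect_true(all(diff(pow) > 0))
  n_req <- correlation_required_n(0.38, power = 0.99, alpha = 0.025)
  expect_gte(correlation_power(0.38, n_req), 0.99)
  expect_lt(correlation_power(0.38, n_req - 1), 0.99)
  # closed-form oracle
  n_cf <- ceiling(((qnorm(1 - 0.025 / 2) + qnorm(0.99)) / atanh(0.38))^2 + 3)
  expect_lte(abs(n_req - n_cf), 1L)
})

test_that("split-half reliability separates signal from noise cohorts", {
  # deterministic participants: accuracy 0 or 1 on every trial
  det <- do.call(rbind, lapply(1:10, function(i)
    data.frame(participant_id = sprintf("D%02d", i),
               correct = rep(i > 5, 30))))
  expect_equal(split_half_reliability(det, n_splits = 50, seed = 1)$reliability, 1)

  # exchangeable participants: same Bernoulli(0.7), no true variance
  set.seed(10)
  same <- do.call(rbind, lapply(1:40, function(i)
    data.frame(participant_id = sprintf("S%02d", i),
               correct = runif(60) < 0.7)))
  r0 <- split_half_reliability(same, n_splits = 200, seed = 2)$reliability
  expect_lt(abs(r0), 0.15)
})

test_that("reliability grows with trial count in a heterogeneous cohort", {
  set.seed(33)
  n_p <- 60
  acc <- pnorm((rnorm(n_p, 1, 0.6)) / 2) # per-participant true accuracy
  rel <- sapply(c(16, 48, 90), function(nt) {
    trials <- do.call(rbind, lapply(seq_len(n_p), function(i)
      data.frame(participant_id = sprintf("H%02d", i),
                 correct = runif(nt) < acc[i])))
    split_half_reliability(trials, n_splits = 120, seed = nt)$reliability
  })
  expect_true(all(diff(rel) > 0))
})
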