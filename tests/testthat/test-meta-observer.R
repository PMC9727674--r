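test_that("joint probabilities normalise for random valid observers", {
  set.seed(11)
  for (i in 1:50) {
    obs <- random_meta_observer()
    for (s in 0:1) {
      p <- conf_probabilities(obs, s)
      expect_equal(sum(p$joint), 1, tolerance = 1e-12)
      expect_equal(unname(rowSums(p$conditional)), c(1, 1), tolerance = 1e-12)
    }
  }
})

test_that("zero meta-sensitivity makes confidence blind to the stimulus", {
  obs <- meta_observer(0, 1.5, 0.3, t2_S1 = -c(0.5, 1, 1.5),
                       t2_S2 = c(0.5, 1, 1.5))
  p0 <- conf_probabilities(obs, 0)
  p1 <- conf_probabilities(obs, 1)
  expect_equal(p0$conditional, p1$conditional, tolerance = 1e-12)
})

test_that("joint cells equal a numerical-integration oracle of the unit normal", {
  # m = 2, c' = 0, thresholds at +/-0.5, +/-1, +/-1.5
  obs <- meta_observer(2, 2, 0, t2_S1 = -c(0.5, 1, 1.5),
                       t2_S2 = c(0.5, 1, 1.5))
  dens_mass <- function(lo, hi, mu) {
    stats::integrate(function(x) dnorm(x, mean = mu), lo, hi,
                     rel.tol = 1e-12)$value
  }
  for (s in 0:1) {
    mu <- (if (s == 1) 1 else -1) * 1 # m/2 = 1
    edges_up <- c(0, 0.5, 1, 1.5, Inf)
    edges_dn <- c(0, -0.5, -1, -1.5, -Inf)
    joint <- conf_probabilities(obs, s)$joint
    for (k in 1:4) {
      expect_equal(joint["1", k], dens_mass(edges_up[k], edges_up[k + 1], mu),
                   tolerance = 1e-8)
      expect_equal(joint["0", k], dens_mass(edges_dn[k + 1], edges_dn[k], mu),
                   tolerance = 1e-8)
    }
  }
})

test_that("threshold ordering violations are rejected", {
  expect_error(meta_observer(1, 1, 0, t2_S1 = c(-1, -0.5, -1.5),
                             t2_S2 = c(0.5, 1, 1.5)), "non-increasing")
  expect_error(meta_observer(1, 1, 0, t2_S1 = -c(0.5, 1, 1.5),
                             t2_S2 = c(1, 0.5, 1.5)), "non-decreasing")
  expect_error(meta_observer(1, 0, 0, t2_S1 = -c(0.5, 1, 1.5),
                             t2_S2 = c(0.5, 1, 1.5)), "d' = 0")
})

test_that("meta_loglik equals a brute-force per-trial product", {
  set.seed(21)
  for (rep in 1:10) {
    obs <- random_meta_observer()
    n <- array(rpois(16, 4), dim = c(2, 2, 4))
    bf <- 0
    for (s in 1:2) {
      cond <- conf_probabilities(obs, s - 1)$conditional
      for (r in 1:2) for (k in 1:4) {
        if (n[s, r, k] > 0) bf <- bf + n[s, r, k] * log(cond[r, k])
      }
    }
    expect_equal(meta_loglik(n, obs), bf, tolerance = 1e-12)
  }
})

test_that("meta_loglik edge cases: empty counts, single count, impossible cell", {
  obs <- meta_observer(1.2, 1.5, 0.1, t2_S1 = 0.08 - c(0.5, 1, 1.5),
                       t2_S2 = 0.08 + c(0.5, 1, 1.5))
  empty <- array(0L, dim = c(2, 2, 4))
  expect_equal(meta_loglik(empty, obs), 0)

  single <- empty; single[2, 2, 3] <- 1L
  expect_equal(meta_loglik(single, obs),
               log(conf_probabilities(obs, 1)$conditional["1", 3]))

  # a threshold far in the tail makes the top bin numerically impossible
  far <- meta_observer(0.5, 1.5, 0, t2_S1 = -c(0.5, 1, 40),
                       t2_S2 = c(0.5, 1, 40))
  imp <- empty; imp[1, 1, 4] <- 3L
  expect_identical(meta_loglik(imp, far), -Inf)
})

test_that("truth maximises the likelihood over a meta-d' grid when counts
           match the model exactly", {
  truth <- meta_observer(1.2, 1.6, 0.2, t2_S1 = 0.15 - c(0.4, 0.9, 1.4),
                         t2_S2 = 0.15 + c(0.4, 0.9, 1.4))
  big <- 1e6
  cnt <- array(0, dim = c(2, 2, 4))
  for (s in 0:1) {
    joint <- conf_probabilities(truth, s)$joint
    cnt[s + 1, 1, ] <- joint["0", ] * big
    cnt[s + 1, 2, ] <- joint["1", ] * big
  }
  # thresholds held at their true absolute positions; only meta-d' varies
  grid <- seq(0.2, 2.4, by = 0.1)
  ll <- vapply(grid, function(m) {
    obs <- meta_observer(m, truth$d_prime, truth$criterion_c,
                         t2_S1 = truth$t2_S1, t2_S2 = truth$t2_S2)
    meta_loglik(cnt, obs)
  }, numeric(1))
  expect_equal(grid[which.max(ll)], 1.2, tolerance = 1e-9)
})
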