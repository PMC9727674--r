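# shared fixture builders; everything is generated in code at test time

make_trial_df <- function(participant_id, phase, stim, resp,
                          correct = stim == resp,
                          confidence = if (phase[1] == "test")
                            rep(3L, length(stim)) else NA_integer_) {
  data.frame(participant_id = participant_id, phase = phase,
             trial_index = seq_along(stim), stim = stim, resp = resp,
             correct = correct, confidence = confidence,
             stringsAsFactors = FALSE)
}

# a small well-formed two-participant table (baseline + test per participant)
two_participant_table <- function() {
  set.seed(99)
  rows <- lapply(c("A", "B"), function(id) {
    nb <- 8L; nt <- 12L
    stim_b <- rbinom(nb, 1, 0.5); resp_b <- rbinom(nb, 1, 0.5)
    stim_t <- rbinom(nt, 1, 0.5); resp_t <- rbinom(nt, 1, 0.5)
    rbind(make_trial_df(id, rep("baseline", nb), stim_b, resp_b),
          make_trial_df(id, rep("test", nt), stim_t, resp_t,
                        confidence = sample(1:4, nt, replace = TRUE)))
  })
  do.call(rbind, rows)
}

write_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE, na = "")
  path
}

# counts tensor whose response marginals give exactly the requested hit and
# false-alarm rates (confidence spread over levels arbitrarily)
counts_from_rates <- function(H, FA, n_per_class = 10000L, K = 4L) {
  cnt <- array(0L, dim = c(2L, 2L, K))
  h1 <- round(H * n_per_class); f1 <- round(FA * n_per_class)
  cnt[2, 2, 1:2] <- c(h1 - h1 %/% 2L, h1 %/% 2L)
  cnt[2, 1, 1] <- n_per_class - h1
  cnt[1, 2, 1:2] <- c(f1 - f1 %/% 2L, f1 %/% 2L)
  cnt[1, 1, 1] <- n_per_class - f1
  structure(cnt, class = c("confidence_counts", "array"))
}

random_meta_observer <- function(K = 4L) {
  m <- runif(1, -2, 3)
  d <- runif(1, 0.3, 3)
  cc <- runif(1, -0.7, 0.7)
  cp <- cc * m / d
  meta_observer(m, d, cc,
                t2_S1 = cp - cumsum(runif(K - 1, 0.1, 1)),
                t2_S2 = cp + cumsum(runif(K - 1, 0.1, 1)))
}

# standardized recursive path data with known coefficients
simulate_path_data <- function(n, a, b, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nm <- length(a)
  SKILL <- rnorm(n)
  M <- sapply(seq_len(nm), function(j)
    a[j] * SKILL + rnorm(n, 0, sqrt(1 - a[j]^2)))
  Sigma_M <- outer(a, a) + diag(1 - a^2)
  psi_y <- 1 - drop(t(b) %*% Sigma_M %*% b)
  stopifnot(psi_y > 0)
  EST_ERR <- drop(M %*% b) + rnorm(n, 0, sqrt(psi_y))
  dat <- cbind(SKILL, M, EST_ERR)
  colnames(dat) <- c("SKILL", c("PERFORM", "M_SENSE", "M_EFFIC",
                                "M_BIAS")[seq_len(nm)], "EST_ERR")
  dat
}
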