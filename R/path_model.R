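#' Specify a recursive skill-to-estimation-error path model
#'
#' The a-priori mediation structure: latent task skill (`SKILL`, measured
#' in the baseline phase) influences self-estimation error (`EST_ERR`)
#' only through a set of mediators measured in the test phase — task
#' performance (`PERFORM`) and the three metacognitive measures
#' (`M_SENSE`, `M_EFFIC`, `M_BIAS`). Each mediator receives an a-path from
#' `SKILL` and sends a b-path to `EST_ERR`; mediator residual covariances
#' are free; there is no direct `SKILL -> EST_ERR` path unless `direct =
#' TRUE`, so the total effect is identically the sum of the indirect
#' effects `a * b`.
#'
#' @param mediators character subset of
#'   `c("PERFORM", "M_SENSE", "M_EFFIC", "M_BIAS")` (order preserved).
#' @param direct include a direct `SKILL -> EST_ERR` path (saturates the
#'   model; off by default).
#' @param exogenous,outcome variable names (defaults `"SKILL"`,
#'   `"EST_ERR"`).
#' @return list of class `"path_model"`.
#' @export
path_model <- function(mediators = c("PERFORM", "M_SENSE", "M_EFFIC", "M_BIAS"),
                       direct = FALSE, exogenous = "SKILL",
                       outcome = "EST_ERR") {
  stopifnot(length(mediators) >= 1L, !anyDuplicated(mediators),
            !exogenous %in% mediators, !outcome %in% mediators)
  structure(list(exogenous = exogenous, mediators = mediators,
                 outcome = outcome, direct = direct,
                 metacog = setdiff(mediators, "PERFORM")),
            class = "path_model")
}

#' Rank-transform and standardise an analysis table
#'
#' Each variable is replaced by its mean-tie ranks and then z-scored.
#' Monotone transforms of a variable leave the output unchanged, which is
#' what lets the downstream path coefficients be read as robust,
#' standardised quantities.
#'
#' @param data `data.frame` or matrix of numeric variables (valid,
#'   non-excluded participants only).
#' @return numeric matrix of standardised ranks, same dimnames.
#' @export
rank_transform <- function(data) {
  m <- as.matrix(data)
  stopifnot(is.numeric(m))
  out <- apply(m, 2, function(col) {
    if (length(unique(col)) < 2L) stop("constant variable cannot be ranked")
    r <- rank(col, ties.method = "average")
    (r - mean(r)) / stats::sd(r)
  })
  dimnames(out) <- dimnames(m)
  out
}

# core estimator on an ML covariance matrix. Columns of S are ordered
# (exogenous, mediators..., outcome). Equation-wise least squares is the
# full-information ML estimator for this recursive structure because the
# likelihood factorises as f(X) f(M | X) f(Y | M [, X]).
path_fit_cov <- function(S, nm, direct) {
  xi <- 1L; mi <- 1L + seq_len(nm); yi <- nm + 2L
  a <- S[xi, mi] / S[xi, xi]
  if (direct) {
    pred <- c(mi, xi)
    coefs <- solve(S[pred, pred], S[pred, yi])
    b <- coefs[seq_len(nm)]; dpath <- coefs[nm + 1L]
  } else {
    b <- solve(S[mi, mi, drop = FALSE], S[mi, yi])
    dpath <- 0
  }
  list(a = a, b = b, direct = dpath, indirect = a * b)
}

# -2-loglik pieces for the implied multivariate-normal model. The implied
# covariance equals S everywhere except the (exogenous, outcome) cell,
# which the no-direct-path structure constrains to sum(a*b) * var(X).
path_loglik <- function(S, n, est, nm, direct) {
  p <- nm + 2L
  Sigma <- S
  if (!direct) {
    Sigma[1L, p] <- Sigma[p, 1L] <- sum(est$a * est$b) * S[1L, 1L]
  }
  chS <- chol(S); chSig <- chol(Sigma)
  logdetS <- 2 * sum(log(diag(chS)))
  logdetSig <- 2 * sum(log(diag(chSig)))
  Sig_inv <- chol2inv(chSig)
  tr <- sum(Sig_inv * S)
  loglik <- -n / 2 * (p * log(2 * pi) + logdetSig + tr)
  chisq <- n * (logdetSig - logdetS + tr - p)
  k <- 2 * nm + direct + nm * (nm - 1) / 2 + nm + 2
  df <- p * (p + 1) / 2 - k
  # adjusted goodness of fit
  M <- Sig_inv %*% S
  gfi <- 1 - sum((M - diag(p))^2) / sum(M^2)
  agfi <- if (df > 0) 1 - (p * (p + 1) / (2 * df)) * (1 - gfi) else NA_real_
  list(loglik = loglik, chisq = max(chisq, 0), df = df, k_params = k,
       AIC = -2 * loglik + 2 * k, gfi = gfi, agfi = agfi)
}

#' Fit a path model with bootstrap confidence intervals
#'
#' Point estimates are maximum likelihood for the recursive
#' observed-variable system (equivalent to equation-wise least squares for
#' this structure). Indirect effects are the `a * b` coefficient products;
#' 95\% confidence intervals come from a participant-resampling percentile
#' bootstrap; the log-likelihood and AIC come from the implied multivariate
#' normal model (covariance structure only, `AIC = -2 loglik + 2 k`).
#'
#' The data are used as given: pass them through [rank_transform()] first
#' for the ranked, standardised analysis.
#'
#' @param data matrix or `data.frame` containing the model's variables by
#'   name; `n > 20` complete rows.
#' @param model a [path_model()].
#' @param n_boot bootstrap resamples (default 5000).
#' @param seed integer seed.
#' @param conf_level CI level (default 0.95).
#' @return list of class `"path_fit"` with `paths` (a `data.frame` of
#'   standardised coefficients and CIs for every a-path, b-path and
#'   indirect effect), `total_metacognition` and `total_effect` (each with
#'   CI), `loglik`, `k_params`, `AIC`, `chisq`, `df`, `agfi`, `n`,
#'   `n_boot`, `n_boot_skipped`, `model`, `seed`.
#' @export
fit_path_model <- function(data, model, n_boot = 5000L, seed = 1L,
                           conf_level = 0.95) {
  stopifnot(inherits(model, "path_model"))
  vars <- c(model$exogenous, model$mediators, model$outcome)
  m <- as.matrix(as.data.frame(data)[, vars, drop = FALSE])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n <= 20L) stop("need more than 20 complete observations")
  nm <- length(model$mediators)
  mc <- intersect(model$metacog, model$mediators)
  mc_idx <- match(mc, model$mediators)

  stat_vec <- function(S) {
    est <- path_fit_cov(S, nm, model$direct)
    c(est$a, est$b, est$indirect,
      total_metacog = if (length(mc_idx)) sum(est$indirect[mc_idx]) else 0,
      total_effect = sum(est$indirect) + est$direct,
      direct = est$direct)
  }
  center <- function(mm) sweep(mm, 2, colMeans(mm))
  S <- crossprod(center(m)) / n
  if (any(diag(S) <= 0)) stop("constant variable in data")
  est <- path_fit_cov(S, nm, model$direct)
  point <- stat_vec(S)
  fitstats <- path_loglik(S, n, est, nm, model$direct)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nstat <- length(point)
  boot <- matrix(NA_real_, n_boot, nstat)
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    mb <- m[sample.int(n, n, replace = TRUE), , drop = FALSE]
    Sb <- crossprod(center(mb)) / n
    if (any(diag(Sb) <= .Machine$double.eps)) { skipped <- skipped + 1L; next }
    res <- tryCatch(stat_vec(Sb), error = function(e) NULL)
    if (is.null(res)) { skipped <- skipped + 1L; next }
    boot[b, ] <- res
  }
  alpha <- (1 - conf_level) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)

  med <- model$mediators
  lab <- c(paste0("a_", med), paste0("b_", med), paste0("indirect_", med),
           "total_metacognition", "total_effect", "direct")
  paths <- data.frame(path = lab, estimate = unname(point),
                      ci_low = ci[1, ], ci_high = ci[2, ],
                      row.names = NULL, stringsAsFactors = FALSE)
  if (!model$direct) paths <- paths[paths$path != "direct", ]
  if (!length(mc_idx)) paths[paths$path == "total_metacognition",
                             c("ci_low", "ci_high")] <- NA_real_

  structure(c(list(paths = paths,
                   total_metacognition = point[["total_metacog"]],
                   total_effect = point[["total_effect"]]),
              fitstats,
              list(n = n, n_boot = n_boot, n_boot_skipped = skipped,
                   model = model, seed = seed, conf_level = conf_level)),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("path model: %s -> {%s} -> %s  (n = %d)\n",
              x$model$exogenous, paste(x$model$mediators, collapse = ", "),
              x$model$outcome, x$n))
  tab <- x$paths
  tab$estimate <- sprintf("% .3f", tab$estimate)
  tab$`95% CI` <- sprintf("(% .3f, % .3f)", tab$ci_low, tab$ci_high)
  print(tab[, c("path", "estimate", "95% CI")], row.names = FALSE)
  cat(sprintf("loglik = %.2f, k = %d, AIC = %.2f, chisq(%d) = %.3f, AGFI = %.3f\n",
              x$loglik, x$k_params, x$AIC, x$df, x$chisq,
              if (is.na(x$agfi)) NA else x$agfi))
  invisible(x)
}

path_ci <- function(fit, path) {
  row <- fit$paths[fit$paths$path == path, ]
  c(row$ci_low, row$ci_high)
}

#' Iterative AIC-guided model reduction
#'
#' Starting from the fitted full model, mediators whose indirect-effect
#' 95\% confidence interval includes zero are candidates for dropping;
#' mediators with a significant indirect effect are never dropped. At each
#' step every single-candidate reduction is fitted, the lowest-AIC
#' candidate is taken (ties broken by fewer parameters, then by the fixed
#' mediator order), and the step is accepted if it lowers the AIC.
#' Dropping a mediator's path removes the mediator from the model, so
#' successive models are compared across their own variable sets — the
#' same trade-off the AIC comparison with the performance-only model uses.
#'
#' @param data as for [fit_path_model()].
#' @param full the starting [path_model()] (default: all four mediators).
#' @param n_boot,seed,conf_level bootstrap settings per fit.
#' @return list: `selected` (final `"path_fit"`), `fits` (every fitted
#'   model along the way), `trace` (`data.frame` log of each decision).
#' @export
reduce_model <- function(data, full = path_model(), n_boot = 5000L,
                         seed = 1L, conf_level = 0.95) {
  fit <- fit_path_model(data, full, n_boot = n_boot,
                        seed = derive_seed(seed, "full"),
                        conf_level = conf_level)
  fits <- list(fit)
  trace <- data.frame(step = 0L, model = paste(full$mediators, collapse = "+"),
                      AIC = fit$AIC, action = "fit full model",
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    step <- step + 1L
    meds <- fit$model$mediators
    if (length(meds) <= 1L) break
    droppable <- vapply(meds, function(mm) {
      ci <- path_ci(fit, paste0("indirect_", mm))
      ci[1] <= 0 && ci[2] >= 0
    }, logical(1))
    cand <- meds[droppable]
    if (!length(cand)) break
    cand_fits <- lapply(cand, function(mm) {
      fit_path_model(data, path_model(setdiff(meds, mm),
                                      direct = fit$model$direct,
                                      exogenous = fit$model$exogenous,
                                      outcome = fit$model$outcome),
                     n_boot = n_boot,
                     seed = derive_seed(seed, paste0("drop-", step, "-", mm)),
                     conf_level = conf_level)
    })
    aics <- vapply(cand_fits, `[[`, numeric(1), "AIC")
    ks <- vapply(cand_fits, `[[`, numeric(1), "k_params")
    best <- order(aics, ks, match(cand, full$mediators))[1]
    if (aics[best] + 1e-6 < fit$AIC) {
      fit <- cand_fits[[best]]
      fits <- c(fits, list(fit))
      trace <- rbind(trace, data.frame(
        step = step, model = paste(fit$model$mediators, collapse = "+"),
        AIC = fit$AIC, action = paste0("dropped ", cand[best]),
        stringsAsFactors = FALSE))
    } else {
      trace <- rbind(trace, data.frame(
        step = step, model = paste(meds, collapse = "+"), AIC = fit$AIC,
        action = "no candidate improved AIC; stopped",
        stringsAsFactors = FALSE))
      break
    }
  }
  list(selected = fit, fits = fits, trace = trace)
}

#' AIC model comparison: Delta-AIC and relative likelihood
#'
#' The AIC increment between two models is converted into the relative
#' likelihood of the lower-AIC model by `exp(delta_aic / 2)`. The result is
#' capped at the largest representable double; a capped value is flagged.
#'
#' @param fit_a,fit_b `"path_fit"` objects, or bare AIC values.
#' @return list: `delta_aic` (higher minus lower AIC, >= 0), `preferred`
#'   (`"a"`, `"b"` or `"tie"` — the lower-AIC model), `relative_likelihood`,
#'   `capped`.
#' @export
#' @examples
#' compare_models(5633, 2748)$delta_aic # 2885
#' round(compare_models(2, 0)$relative_likelihood, 2) # 2.72
compare_models <- function(fit_a, fit_b) {
  aic_a <- if (inherits(fit_a, "path_fit")) fit_a$AIC else as.numeric(fit_a)
  aic_b <- if (inherits(fit_b, "path_fit")) fit_b$AIC else as.numeric(fit_b)
  delta <- abs(aic_a - aic_b)
  rl <- exp(delta / 2)
  capped <- !is.finite(rl)
  if (capped) rl <- .Machine$double.xmax
  list(delta_aic = delta,
       preferred = if (aic_a < aic_b) "a" else if (aic_b < aic_a) "b" else "tie",
       relative_likelihood = rl, capped = capped)
}

#' Fit the performance-only comparison model
#'
#' The maximally simple account: `SKILL -> PERFORM -> EST_ERR`, with no
#' metacognitive paths. Its total effect equals its single indirect path.
#'
#' @inheritParams fit_path_model
#' @return a `"path_fit"`.
#' @export
performance_only_model <- function(data, n_boot = 5000L, seed = 1L,
                                   conf_level = 0.95) {
  fit_path_model(data, path_model("PERFORM"), n_boot = n_boot, seed = seed,
                 conf_level = conf_level)
}
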