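#' Read a trial table and (optionally) global self-estimates
#'
#' The trial table is UTF-8 delimited text with a header naming the columns
#' `participant_id`, `phase`, `trial_index`, `stim`, `resp`, `correct` and
#' `confidence`. `phase` is `"baseline"` or `"test"`; `stim` and `resp` are
#' the binary class labels 0/1 (the class of a 2AFC trial is the screen
#' position of the correct option); `correct` is logical (or 0/1) and must
#' equal `stim == resp`; `confidence` is an integer on the 1..K rating scale
#' (1 = very uncertain, K = very certain), present on every test trial and
#' empty on every baseline trial.
#'
#' Structural problems (a missing column) are errors. Row-level problems are
#' not: invalid rows are dropped and reported, with their file row numbers,
#' in the `rejected` component, so a handful of corrupt rows never aborts a
#' whole study load.
#'
#' @param path path to the trial table.
#' @param estimates_path optional path to the self-estimates table, columns
#'   `participant_id`, `relative_estimate` (percentile, 1-100) and
#'   `absolute_estimate` (score, 0-100).
#' @param delim field delimiter, default comma.
#' @param K number of confidence levels (default 4).
#' @return a list of class `"trial_data"` with components
#'   \describe{
#'     \item{trials}{validated trial `data.frame`, ordered as read}
#'     \item{estimates}{self-estimate `data.frame` or `NULL`}
#'     \item{rejected}{`data.frame` with `row` (file row number, counting the
#'       header as row 1) and `reason` for every dropped trial row}
#'   }
#' @export
read_trials <- function(path, estimates_path = NULL, delim = ",", K = 4L) {
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", na.strings = c("NA", ""),
                           stringsAsFactors = FALSE)
  needed <- c("participant_id", "phase", "trial_index", "stim", "resp",
              "correct", "confidence")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("trial table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  trials <- data.frame(
    participant_id = raw$participant_id,
    phase = raw$phase,
    trial_index = suppressWarnings(as.integer(raw$trial_index)),
    stim = suppressWarnings(as.integer(raw$stim)),
    resp = suppressWarnings(as.integer(raw$resp)),
    correct = parse_logical(raw$correct),
    confidence = suppressWarnings(as.integer(raw$confidence)),
    stringsAsFactors = FALSE
  )
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reason))
    reason[bad] <<- why
  }
  flag(is.na(trials$participant_id), "missing participant_id")
  flag(!(trials$phase %in% c("baseline", "test")), "unknown phase")
  flag(is.na(trials$trial_index) | trials$trial_index < 1L, "bad trial_index")
  flag(!(trials$stim %in% c(0L, 1L)), "stim not in {0,1}")
  flag(!(trials$resp %in% c(0L, 1L)), "missing or invalid resp")
  flag(is.na(trials$correct), "missing correct flag")
  ok <- is.na(reason)
  flag(ok & trials$correct != (trials$stim == trials$resp),
       "correct inconsistent with stim/resp")
  is_test <- trials$phase == "test"
  flag(is_test & is.na(trials$confidence), "test row without confidence")
  flag(is_test & !is.na(trials$confidence) &
         (trials$confidence < 1L | trials$confidence > K),
       "confidence out of range")
  flag(!is_test & !is.na(trials$confidence), "baseline row with confidence")

  bad <- !is.na(reason)
  rejected <- data.frame(row = which(bad) + 1L, reason = reason[bad],
                         stringsAsFactors = FALSE)
  trials <- trials[!bad, , drop = FALSE]
  rownames(trials) <- NULL

  estimates <- NULL
  if (!is.null(estimates_path)) {
    est <- utils::read.table(estimates_path, header = TRUE, sep = delim,
                             stringsAsFactors = FALSE)
    eneed <- c("participant_id", "relative_estimate", "absolute_estimate")
    if (!all(eneed %in% names(est))) {
      stop("estimates table is missing column(s): ",
           paste(setdiff(eneed, names(est)), collapse = ", "))
    }
    estimates <- validate_estimates(est[eneed])
  }
  structure(list(trials = trials, estimates = estimates, rejected = rejected),
            class = "trial_data")
}

parse_logical <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0")] <- FALSE
  out
}

validate_estimates <- function(est) {
  est$relative_estimate <- as.numeric(est$relative_estimate)
  est$absolute_estimate <- as.numeric(est$absolute_estimate)
  bad_rel <- !is.na(est$relative_estimate) &
    (est$relative_estimate < 1 | est$relative_estimate > 100)
  bad_abs <- !is.na(est$absolute_estimate) &
    (est$absolute_estimate < 0 | est$absolute_estimate > 100)
  if (any(bad_rel)) stop("relative_estimate outside [1, 100] for participant(s): ",
                         paste(est$participant_id[bad_rel], collapse = ", "))
  if (any(bad_abs)) stop("absolute_estimate outside [0, 100] for participant(s): ",
                         paste(est$participant_id[bad_abs], collapse = ", "))
  est
}

#' Write trial and estimate tables
#'
#' Inverse of [read_trials()]: writes the standard delimited-text formats,
#' reproducing a read table up to column order.
#'
#' @param trial_data a `"trial_data"` list, or a trial `data.frame`.
#' @param path output path for the trial table.
#' @param estimates_path optional output path for the estimates table.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trial_data, path, estimates_path = NULL, delim = ",") {
  trials <- if (inherits(trial_data, "trial_data")) trial_data$trials else trial_data
  out <- trials[, c("participant_id", "phase", "trial_index", "stim", "resp",
                    "correct", "confidence")]
  utils::write.table(out, path, sep = delim, row.names = FALSE, quote = FALSE,
                     na = "")
  if (!is.null(estimates_path)) {
    est <- if (inherits(trial_data, "trial_data")) trial_data$estimates else NULL
    if (is.null(est)) stop("no estimates to write")
    utils::write.table(est, estimates_path, sep = delim, row.names = FALSE,
                       quote = FALSE, na = "")
  }
  invisible(path)
}

#' Tally confidence ratings into the count tensor used by the meta-d' likelihood
#'
#' Builds the `n(conf = x | stim = i, resp = j)` tally that the type-2
#' multinomial likelihood consumes: a `2 x 2 x K` array of nonnegative
#' counts, dimensions `stim` (0, 1), `resp` (0, 1) and `conf` (1..K).
#'
#' @param trials test-phase trial rows for a single participant (`data.frame`
#'   with `stim`, `resp`, `confidence`).
#' @param K number of confidence levels.
#' @return an integer array of class `"confidence_counts"`, summing to
#'   `nrow(trials)`.
#' @export
tally_confidence <- function(trials, K = 4L) {
  if (nrow(trials) == 0L) stop("no test trials to tally")
  if (any(is.na(trials$confidence))) stop("test trials must all carry a confidence rating")
  if (any(trials$confidence < 1L | trials$confidence > K)) {
    stop("confidence outside 1..", K)
  }
  counts <- table(factor(trials$stim, levels = 0:1),
                  factor(trials$resp, levels = 0:1),
                  factor(trials$confidence, levels = seq_len(K)))
  counts <- array(as.integer(counts), dim = c(2L, 2L, K),
                  dimnames = list(stim = c("0", "1"), resp = c("0", "1"),
                                  conf = as.character(seq_len(K))))
  structure(counts, class = c("confidence_counts", "array"))
}
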