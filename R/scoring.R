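# Trial cleaning, condition summaries and the inhibition difference
# scores. Percentages are carried on a 0-100 scale throughout; the
# adjusted AccD divides by the prepotent *proportion* correct (pct/100).

#' Clean a session's trials into accuracy and reaction-time sets
#'
#' Applies the coded-validity rules: trials with an RT below the variant's
#' floor are invalid (`invalid_fast`) and enter neither set; externally
#' coded invalid trials (finger at onset, intervention, accidental touch)
#' enter neither set; the first trial of a toddler session is discarded.
#' The accuracy set is everything that survives. The RT set additionally
#' requires a correct response and an RT below the 5000 ms ceiling.
#'
#' @param session An `ecitt_session` (see [simulate_session()] /
#'   [read_session()]).
#' @param variant An [ecitt_variant()]; defaults to the variant named in
#'   the session header.
#' @return A list with data.frames `accuracy_set` and `rt_set`.
#' @export
clean_trials <- function(session, variant = NULL) {
  stopifnot(inherits(session, "ecitt_session"))
  if (is.null(variant)) variant <- ecitt_variant(session$header$variant)
  tr <- session$trials
  if (nrow(tr) == 0L)
    return(list(accuracy_set = tr, rt_set = tr))
  # defensive recode: a sub-floor RT is invalid_fast whatever the file says
  fast <- !is.na(tr$rt_ms) & tr$rt_ms < variant$rt_floor_ms
  tr$validity[fast] <- "invalid_fast"
  keep <- tr$validity == "valid"
  if (variant$discard_first_trial) {
    first <- which(tr$block == min(tr$block))[
      which.min(tr$trial[tr$block == min(tr$block)])]
    keep[first] <- FALSE
  }
  accuracy_set <- tr[keep, , drop = FALSE]
  rt_ok <- accuracy_set$correct & !is.na(accuracy_set$rt_ms) &
    accuracy_set$rt_ms < variant$rt_ceiling_ms
  list(accuracy_set = accuracy_set,
       rt_set = accuracy_set[rt_ok, , drop = FALSE])
}

#' Per-condition accuracy and reaction-time summaries
#'
#' @param accuracy_set,rt_set Output of [clean_trials()].
#' @return A data.frame with one row per condition (`prepotent`,
#'   `inhibitory`) and columns `n_valid`, `n_correct`, `pct_correct`,
#'   `n_rt_trials`, `median_rt_ms` (NA when no scorable RT trial exists;
#'   the median of an even count is the mean of the two central values).
#' @export
summarize_conditions <- function(accuracy_set, rt_set) {
  conds <- c("prepotent", "inhibitory")
  rows <- lapply(conds, function(cn) {
    a <- accuracy_set[accuracy_set$condition == cn, , drop = FALSE]
    r <- rt_set[rt_set$condition == cn, , drop = FALSE]
    data.frame(
      condition = cn,
      n_valid = nrow(a),
      n_correct = sum(a$correct),
      pct_correct = if (nrow(a) > 0L) 100 * sum(a$correct) / nrow(a)
                    else NA_real_,
      n_rt_trials = nrow(r),
      median_rt_ms = if (nrow(r) > 0L) stats::median(r$rt_ms)
                     else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Inhibition difference scores for one session
#'
#' Computes the accuracy difference score
#' \eqn{AccD = \%correct_{prepotent} - \%correct_{inhibitory}} (higher =
#' poorer inhibition), the adjusted AccD (AccD divided by the prepotent
#' proportion correct, correcting for weak prepotency), and the
#' reaction-time difference \eqn{RTD = median RT_{inhibitory} - median
#' RT_{prepotent}} on correct trials. A session is included only when
#' prepotent accuracy is strictly above 60% (at exactly 60% a prepotent
#' response tendency cannot be assumed and the session is excluded).
#'
#' @param summaries Output of [summarize_conditions()].
#' @return A one-row data.frame of class `ecitt_scores` with columns
#'   `accd`, `accd_adjusted`, `rtd_ms`, `included`, `exclusion_reason`
#'   plus the per-condition summary columns.
#' @export
inhibition_scores <- function(summaries) {
  p <- summaries[summaries$condition == "prepotent", ]
  i <- summaries[summaries$condition == "inhibitory", ]
  reason <- NA_character_
  accd <- accd_adj <- rtd <- NA_real_
  if (p$n_valid == 0L || i$n_valid == 0L) {
    reason <- "no valid trials in a condition"
  } else {
    accd <- p$pct_correct - i$pct_correct
    if (p$pct_correct > 0)
      accd_adj <- accd / (p$pct_correct / 100)
    if (!is.na(p$median_rt_ms) && !is.na(i$median_rt_ms))
      rtd <- i$median_rt_ms - p$median_rt_ms
  }
  included <- !is.na(p$pct_correct) && p$pct_correct > 60
  if (!included && is.na(reason))
    reason <- "not over 60% correct on prepotent trials"
  out <- data.frame(
    accd = accd, accd_adjusted = accd_adj, rtd_ms = rtd,
    included = included, exclusion_reason = reason,
    prepotent_n_valid = p$n_valid, prepotent_pct_correct = p$pct_correct,
    prepotent_median_rt_ms = p$median_rt_ms,
    inhibitory_n_valid = i$n_valid,
    inhibitory_pct_correct = i$pct_correct,
    inhibitory_median_rt_ms = i$median_rt_ms,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ecitt_scores", "data.frame")
  out
}

#' Score one session end to end
#'
#' Convenience wrapper: [clean_trials()], [summarize_conditions()],
#' [inhibition_scores()], with the session metadata attached.
#'
#' @param session An `ecitt_session`.
#' @param variant Optional [ecitt_variant()] override.
#' @return A one-row `ecitt_scores` data.frame with `participant_id`,
#'   `visit`, `variant` prepended.
#' @export
score_session <- function(session, variant = NULL) {
  sets <- clean_trials(session, variant)
  sc <- inhibition_scores(summarize_conditions(sets$accuracy_set,
                                               sets$rt_set))
  out <- cbind(data.frame(participant_id = session$header$participant_id,
                          visit = session$header$visit,
                          age_months = session$header$age_months,
                          variant = session$header$variant,
                          stringsAsFactors = FALSE),
               sc)
  class(out) <- c("ecitt_scores", "data.frame")
  out
}

#' Score a list of sessions
#'
#' @param sessions List of `ecitt_session` objects (e.g. from
#'   [simulate_cohort()]).
#' @param variant Optional [ecitt_variant()] override.
#' @return An `ecitt_scores` data.frame, one row per session.
#' @export
score_sessions <- function(sessions, variant = NULL) {
  out <- do.call(rbind, lapply(sessions, score_session, variant = variant))
  class(out) <- c("ecitt_scores", "data.frame")
  out
}

#' @export
print.ecitt_scores <- function(x, digits = 2L, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1L))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Flag reaction-time difference outliers
#'
#' Explicitly flags (never silently removes) sessions whose score is more
#' than `k` standard deviations from the group mean, the convention used
#' for longitudinal RT stability analyses.
#'
#' @param scores An `ecitt_scores` data.frame.
#' @param column Score column to screen (default `"rtd_ms"`).
#' @param k SD multiplier (default 3).
#' @return `scores` with a logical `outlier` column appended.
#' @export
flag_outliers <- function(scores, column = "rtd_ms", k = 3) {
  x <- scores[[column]]
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  scores$outlier <- !is.na(x) & abs(x - m) > k * s
  scores
}
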