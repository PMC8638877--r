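# Stop-signal task engine: sub-block sequence construction, the +/-50 ms
# one-up/one-down SSD staircase, and SSRT estimation under the
# independent horse-race model (go and stop processes race; the response
# is withheld iff the stop process, started at the stop-signal delay,
# finishes first).

#' Stop-signal task configuration
#'
#' Defaults follow the standard tablet administration: 5 blocks of 64
#' trials, each block split into 4 sub-blocks of 16 trials holding 12 go
#' and 4 stop trials; the stop-signal delay (SSD) moves in 50 ms steps.
#' The initial SSD (250 ms) and the clamping bounds (0--1150 ms) are
#' package choices and configurable.
#'
#' @param n_blocks,subblocks_per_block,trials_per_subblock,go_per_subblock,stop_per_subblock
#'   Trial-structure counts.
#' @param ssd_step_ms Staircase step (ms).
#' @param ssd_init_ms Starting SSD (ms).
#' @param ssd_bounds_ms Length-2 numeric, SSD clamping bounds (ms).
#' @param n_practice Practice trials (recorded for completeness; not
#'   simulated).
#' @param fixation_delay_ms Fixed pre-stimulus delay (ms).
#' @param ssd50_estimator How "SSD at 50% stopping" is operationalised on
#'   the second half of sub-blocks: `"mean_ssd"` (mean SSD over stop
#'   trials; the tracking estimator, default), `"last_ssd"`, or
#'   `"reversal_midpoint"` (mean of the SSDs at staircase reversals).
#' @return An object of class `sst_config`.
#' @export
sst_config <- function(n_blocks = 5L, subblocks_per_block = 4L,
                       trials_per_subblock = 16L, go_per_subblock = 12L,
                       stop_per_subblock = 4L, ssd_step_ms = 50,
                       ssd_init_ms = 250, ssd_bounds_ms = c(0, 1150),
                       n_practice = 16L, fixation_delay_ms = 500,
                       ssd50_estimator = c("mean_ssd", "last_ssd",
                                           "reversal_midpoint")) {
  ssd50_estimator <- match.arg(ssd50_estimator)
  if (go_per_subblock + stop_per_subblock != trials_per_subblock)
    stop("go + stop trials must equal trials_per_subblock", call. = FALSE)
  if (ssd_step_ms <= 0) stop("ssd_step_ms must be positive", call. = FALSE)
  if (ssd_bounds_ms[1L] < 0 || ssd_bounds_ms[2L] <= ssd_bounds_ms[1L])
    stop("ssd_bounds_ms must be an increasing pair with floor >= 0",
         call. = FALSE)
  structure(list(
    n_blocks = as.integer(n_blocks),
    subblocks_per_block = as.integer(subblocks_per_block),
    trials_per_subblock = as.integer(trials_per_subblock),
    go_per_subblock = as.integer(go_per_subblock),
    stop_per_subblock = as.integer(stop_per_subblock),
    ssd_step_ms = ssd_step_ms,
    ssd_init_ms = ssd_init_ms,
    ssd_bounds_ms = ssd_bounds_ms,
    n_practice = as.integer(n_practice),
    fixation_delay_ms = fixation_delay_ms,
    ssd50_estimator = ssd50_estimator
  ), class = "sst_config")
}

#' Race-model parameters for a simulated stop-signal participant
#'
#' @param go_rt Named vector `c(mu, sigma, tau)`: ex-Gaussian parameters
#'   of the go process finishing time (ms).
#' @param ssrt_true True stop-signal reaction time (ms); the stop process
#'   finishes `ssd + ssrt_true` after the go stimulus.
#' @param p_trigger_failure Probability that the stop process is never
#'   triggered on a stop trial (default 0).
#' @return An object of class `race_params`.
#' @export
race_params <- function(go_rt = c(mu = 450, sigma = 50, tau = 100),
                        ssrt_true = 250, p_trigger_failure = 0) {
  if (!all(c("mu", "sigma", "tau") %in% names(go_rt)))
    stop("go_rt needs named components mu, sigma, tau", call. = FALSE)
  if (ssrt_true <= 0) stop("ssrt_true must be positive", call. = FALSE)
  if (p_trigger_failure < 0 || p_trigger_failure > 1)
    stop("p_trigger_failure must lie in [0, 1]", call. = FALSE)
  structure(list(go_rt = go_rt[c("mu", "sigma", "tau")],
                 ssrt_true = ssrt_true,
                 p_trigger_failure = p_trigger_failure),
            class = "race_params")
}

#' Simulate a single stop trial under the independent race model
#'
#' Draws a go finishing time from the ex-Gaussian go distribution; the
#' response is inhibited iff the stop process wins the race
#' (`ssd + ssrt_true < go time`) and no trigger failure occurs.
#'
#' @param params A [race_params()].
#' @param ssd Stop-signal delay (ms), non-negative.
#' @return A list with `inhibited` (logical) and `rt` (the go RT when the
#'   participant responded, otherwise `NA`).
#' @export
simulate_stop_trial <- function(params, ssd) {
  stopifnot(inherits(params, "race_params"), ssd >= 0)
  go <- .rexgauss(1L, params$go_rt[["mu"]], params$go_rt[["sigma"]],
                  params$go_rt[["tau"]])
  triggered <- stats::runif(1L) >= params$p_trigger_failure
  inhibited <- triggered && (ssd + params$ssrt_true < go)
  list(inhibited = inhibited, rt = if (inhibited) NA_real_ else go)
}

#' Build a stop-signal trial sequence
#'
#' Each sub-block holds exactly the configured numbers of go and stop
#' trials in seeded random order, with left/right directions balanced
#' within sub-block (as evenly as the counts allow).
#'
#' @param config An [sst_config()].
#' @param seed Integer seed.
#' @return A data.frame with columns `subblock` (0-based, across the
#'   whole run), `trial` (0-based within sub-block), `is_stop`,
#'   `direction`.
#' @export
build_sst_sequence <- function(config, seed) {
  stopifnot(inherits(config, "sst_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n_sub <- config$n_blocks * config$subblocks_per_block
  balanced <- function(n) sample(rep_len(c("left", "right"), n))
  out <- lapply(seq_len(n_sub) - 1L, function(sb) {
    is_stop <- sample(c(rep(TRUE, config$stop_per_subblock),
                        rep(FALSE, config$go_per_subblock)))
    dir <- character(length(is_stop))
    dir[is_stop] <- balanced(config$stop_per_subblock)
    dir[!is_stop] <- balanced(config$go_per_subblock)
    data.frame(subblock = sb, trial = seq_along(is_stop) - 1L,
               is_stop = is_stop, direction = dir,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the SSD staircase over a trial sequence
#'
#' Simulates a race-model participant through the sequence. On stop
#' trials the SSD increases by one step after a successful inhibition and
#' decreases by one step after a failed stop, clamped to the configured
#' bounds; go trials draw a (directionally correct) go RT. The staircase
#' thereby tracks the SSD at which stopping succeeds on about half the
#' stop trials.
#'
#' @param specs Output of [build_sst_sequence()].
#' @param params A [race_params()].
#' @param config The [sst_config()] used to build `specs`.
#' @param seed Optional integer seed for the participant's behaviour.
#' @return An object of class `sst_result`: list with `trials` (the
#'   trial table with `ssd_ms`, `responded`, `rt_ms` filled in),
#'   `ssd_trajectory` (SSD at each stop trial), and the summary fields
#'   `ssd_at_50_ms`, `median_go_rt_ms`, `pct_stopped`, `ssrt_ms` computed
#'   by [estimate_ssrt()] on the second half of sub-blocks.
#' @export
run_staircase <- function(specs, params, config, seed = NULL) {
  stopifnot(inherits(params, "race_params"), inherits(config, "sst_config"))
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
  }
  n <- nrow(specs)
  ssd <- config$ssd_init_ms
  ssd_ms <- rep(NA_real_, n)
  responded <- logical(n)
  rt_ms <- rep(NA_real_, n)
  trajectory <- numeric(0L)
  for (i in seq_len(n)) {
    if (specs$is_stop[i]) {
      ssd_ms[i] <- ssd
      trajectory <- c(trajectory, ssd)
      out <- simulate_stop_trial(params, ssd)
      responded[i] <- !out$inhibited
      rt_ms[i] <- out$rt
      ssd <- ssd + if (out$inhibited) config$ssd_step_ms
                   else -config$ssd_step_ms
      ssd <- min(max(ssd, config$ssd_bounds_ms[1L]),
                 config$ssd_bounds_ms[2L])
    } else {
      responded[i] <- TRUE
      rt_ms[i] <- .rexgauss(1L, params$go_rt[["mu"]],
                            params$go_rt[["sigma"]],
                            params$go_rt[["tau"]])
    }
  }
  trials <- specs
  trials$ssd_ms <- ssd_ms
  trials$responded <- responded
  trials$response_correct <- responded & !specs$is_stop
  trials$rt_ms <- rt_ms
  res <- structure(list(trials = trials, ssd_trajectory = trajectory,
                        config = config),
                   class = "sst_result")
  est <- estimate_ssrt(res, config)
  res[names(est)] <- est
  res
}

#' Estimate SSRT from a staircase run
#'
#' Over the second half of sub-blocks (where the staircase has
#' stabilised): the SSD at 50% correct stopping is estimated from the
#' stop-trial SSDs (by the configured estimator, default their mean), the
#' median go RT is computed over responded go trials in the same window,
#' and SSRT is their difference. The percentage of successfully stopped
#' stop trials in the window is also reported.
#'
#' @param result An `sst_result` (or any list with a `trials` table).
#' @param config The [sst_config()].
#' @return List with `ssd_at_50_ms`, `median_go_rt_ms`, `pct_stopped`,
#'   `ssrt_ms`.
#' @export
estimate_ssrt <- function(result, config) {
  tr <- result$trials
  n_sub <- max(tr$subblock) + 1L
  window <- tr$subblock >= n_sub / 2
  stop_tr <- tr[window & tr$is_stop, , drop = FALSE]
  go_tr <- tr[window & !tr$is_stop & tr$responded, , drop = FALSE]
  if (nrow(stop_tr) == 0L || nrow(go_tr) == 0L)
    stop("second-half window holds no scorable trials", call. = FALSE)
  ssd50 <- switch(config$ssd50_estimator,
    mean_ssd = mean(stop_tr$ssd_ms),
    last_ssd = stop_tr$ssd_ms[nrow(stop_tr)],
    reversal_midpoint = {
      s <- stop_tr$ssd_ms
      dirs <- sign(diff(s))
      dirs <- dirs[dirs != 0]
      rev_idx <- which(diff(dirs) != 0) + 1L
      if (length(rev_idx) >= 1L) mean(s[rev_idx + 1L], na.rm = TRUE)
      else mean(s)
    })
  med_go <- stats::median(go_tr$rt_ms)
  list(ssd_at_50_ms = ssd50,
       median_go_rt_ms = med_go,
       pct_stopped = 100 * mean(!stop_tr$responded),
       ssrt_ms = med_go - ssd50)
}

#' @export
print.sst_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<sst_result> %d trials (%d stop); second half: %.1f%% stopped, ",
    "SSD50 = %.0f ms, median go RT = %.0f ms, SSRT = %.0f ms\n"),
    nrow(x$trials), sum(x$trials$is_stop), x$pct_stopped, x$ssd_at_50_ms,
    x$median_go_rt_ms, x$ssrt_ms))
  invisible(x)
}

#' Median of simple reaction times
#'
#' Summary measure for the simple reaction time task; the median of an
#' even count is the mean of the two central values (the same convention
#' as session scoring).
#'
#' @param rts Numeric vector of RTs (ms), at least one.
#' @return The median (ms).
#' @export
simple_rt_summary <- function(rts) {
  rts <- rts[!is.na(rts)]
  if (length(rts) == 0L) stop("no reaction times supplied", call. = FALSE)
  stats::median(rts)
}
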