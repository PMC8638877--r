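#' Block configuration for trial-sequence generation
#'
#' Describes one experimental block of the inhibitory touchscreen task:
#' how many trials it contains, how many of them are inhibitory (smiley at
#' the non-prepotent location), the forced prepotent lead-in, and the
#' maximum allowed run lengths of consecutive same-condition trials.
#' Run caps apply within a block; runs never carry across block boundaries.
#'
#' @param n_trials Trials per block.
#' @param n_inhibitory Inhibitory trials per block (must be < `n_trials`).
#' @param lead_in Number of forced prepotent trials at the start of the
#'   block (the constrained randomisation may place further prepotent
#'   trials after it).
#' @param max_run_prepotent Maximum allowed run of consecutive prepotent
#'   trials.
#' @param max_run_inhibitory Maximum allowed run of consecutive inhibitory
#'   trials (at least 1).
#' @param n_blocks Number of blocks per session.
#' @return An object of class `block_config`.
#' @examples
#' block_config()               # toddler task: 1 block of 32 (24/8)
#' block_config(n_blocks = 3)   # adult task: 3 blocks of 32
#' @export
block_config <- function(n_trials = 32L, n_inhibitory = 8L, lead_in = 3L,
                         max_run_prepotent = 5L, max_run_inhibitory = 2L,
                         n_blocks = 1L) {
  cfg <- list(
    n_trials = as.integer(n_trials),
    n_inhibitory = as.integer(n_inhibitory),
    lead_in = as.integer(lead_in),
    max_run_prepotent = as.integer(max_run_prepotent),
    max_run_inhibitory = as.integer(max_run_inhibitory),
    n_blocks = as.integer(n_blocks)
  )
  if (any(vapply(cfg, is.na, logical(1L))))
    stop("block_config fields must be non-missing integers", call. = FALSE)
  if (cfg$n_trials < 1L || cfg$n_blocks < 1L)
    stop("n_trials and n_blocks must be positive", call. = FALSE)
  if (cfg$n_inhibitory < 0L || cfg$n_inhibitory >= cfg$n_trials)
    stop("n_inhibitory must satisfy 0 <= n_inhibitory < n_trials",
         call. = FALSE)
  if (cfg$lead_in < 0L || cfg$lead_in > cfg$n_trials - cfg$n_inhibitory)
    stop("lead_in must satisfy 0 <= lead_in <= n_trials - n_inhibitory",
         call. = FALSE)
  if (cfg$max_run_prepotent < 1L || cfg$max_run_inhibitory < 1L)
    stop("run caps must be at least 1", call. = FALSE)
  class(cfg) <- "block_config"
  cfg
}

#' Task variant definitions
#'
#' The three task variants share the same block structure and differ in
#' pacing, incorrect-response behaviour and reaction-time validity window:
#' \describe{
#'   \item{ECITT_S1}{toddler version; an incorrect press blanks the screen
#'     for 1 s, the next trial then starts; RT floor 300 ms; the first
#'     (pointed-to) trial is discarded from analysis.}
#'   \item{ECITT_S2}{toddler version in which the incorrect button is
#'     completely unresponsive -- the trial only ends on a correct press,
#'     and scoring uses the first touch; RT floor 300 ms; first trial
#'     discarded.}
#'   \item{ECITT_A}{faster-paced version for children and adults; 3 blocks
#'     of 32 trials, next trial 1000 ms after the previous response; RT
#'     floor 200 ms; no first-trial discard (a practice block is used
#'     instead).}
#' }
#' All variants share the 5000 ms RT ceiling for reaction-time analyses.
#'
#' @param name One of `"ECITT_S1"`, `"ECITT_S2"`, `"ECITT_A"`.
#' @return An object of class `ecitt_variant` with fields `name`,
#'   `incorrect_behavior`, `rt_floor_ms`, `rt_ceiling_ms`,
#'   `discard_first_trial` and the default `config` (a [block_config()]).
#' @export
ecitt_variant <- function(name = c("ECITT_S1", "ECITT_S2", "ECITT_A")) {
  name <- match.arg(name)
  v <- switch(name,
    ECITT_S1 = list(name = name, incorrect_behavior = "blank_1s",
                    rt_floor_ms = 300L, rt_ceiling_ms = 5000L,
                    discard_first_trial = TRUE,
                    config = block_config(n_blocks = 1L)),
    ECITT_S2 = list(name = name, incorrect_behavior = "unresponsive",
                    rt_floor_ms = 300L, rt_ceiling_ms = 5000L,
                    discard_first_trial = TRUE,
                    config = block_config(n_blocks = 1L)),
    ECITT_A  = list(name = name, incorrect_behavior = "next_after_iti",
                    rt_floor_ms = 200L, rt_ceiling_ms = 5000L,
                    discard_first_trial = FALSE,
                    config = block_config(n_blocks = 3L))
  )
  class(v) <- "ecitt_variant"
  v
}

#' @export
print.ecitt_variant <- function(x, ...) {
  cat(sprintf(
    "<%s> %d block(s) of %d trials (%d inhibitory), RT window [%d, %d) ms%s\n",
    x$name, x$config$n_blocks, x$config$n_trials, x$config$n_inhibitory,
    x$rt_floor_ms, x$rt_ceiling_ms,
    if (x$discard_first_trial) ", first trial discarded" else ""))
  invisible(x)
}

#' Counterbalance the prepotent location across participants
#'
#' Alternates the prepotent button location (top / bottom) across
#' participants in input order, so that the two locations are assigned as
#' evenly as possible. The assignment is deterministic given the input
#' order; a participant keeps the same location across longitudinal
#' sessions by re-using their entry.
#'
#' @param participant_ids Character (or coercible) vector of unique ids.
#' @return A data.frame with columns `participant_id` and
#'   `prepotent_location`.
#' @examples
#' assign_counterbalance(c("p1", "p2", "p3"))
#' @export
assign_counterbalance <- function(participant_ids) {
  ids <- as.character(participant_ids)
  if (length(ids) == 0L) stop("participant_ids must be non-empty",
                              call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate participant ids", call. = FALSE)
  data.frame(
    participant_id = ids,
    prepotent_location = rep_len(c("top", "bottom"), length(ids)),
    stringsAsFactors = FALSE
  )
}

#' A single participant's counterbalance entry
#'
#' @param participant_id Identifier.
#' @param prepotent_location `"top"` or `"bottom"`.
#' @return A one-row data.frame matching [assign_counterbalance()] output.
#' @export
counterbalance <- function(participant_id,
                           prepotent_location = c("top", "bottom")) {
  prepotent_location <- match.arg(prepotent_location)
  data.frame(participant_id = as.character(participant_id),
             prepotent_location = prepotent_location,
             stringsAsFactors = FALSE)
}

# opposite screen location
.other_location <- function(loc) ifelse(loc == "top", "bottom", "top")
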