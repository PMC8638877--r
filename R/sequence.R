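# Constrained trial-sequence generation.
#
# Sampling is exactly uniform over the set of constraint-satisfying
# sequences: a memoised dynamic program counts the number of valid
# completions from each state (trials left, inhibitory trials left, current
# run condition and length), and each trial is drawn with probability
# proportional to the completion counts. A zero count at the root signals
# an unsatisfiable configuration.

.count_completions <- function(pos_left, inh_left, last, run, cfg, memo) {
  if (pos_left == 0L) return(as.numeric(inh_left == 0L))
  key <- paste(pos_left, inh_left, last, run, sep = ".")
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  total <- 0
  # place a prepotent trial (need room for the remaining inhibitory trials)
  if (!(last == "P" && run >= cfg$max_run_prepotent) &&
      pos_left - 1L >= inh_left) {
    total <- total + .count_completions(
      pos_left - 1L, inh_left,
      "P", if (last == "P") run + 1L else 1L, cfg, memo)
  }
  # place an inhibitory trial
  if (inh_left > 0L && !(last == "I" && run >= cfg$max_run_inhibitory)) {
    total <- total + .count_completions(
      pos_left - 1L, inh_left - 1L,
      "I", if (last == "I") run + 1L else 1L, cfg, memo)
  }
  memo[[key]] <- total
  total
}

# sample one block's condition vector ("prepotent"/"inhibitory"),
# uniform over the valid set; assumes RNG state is set by the caller
.sample_block_conditions <- function(cfg) {
  if (cfg$lead_in > cfg$max_run_prepotent)
    stop("unsatisfiable config: lead_in exceeds max_run_prepotent",
         call. = FALSE)
  memo <- new.env(parent = emptyenv())
  conds <- character(cfg$n_trials)
  if (cfg$lead_in > 0L) conds[seq_len(cfg$lead_in)] <- "prepotent"
  last <- "P"; run <- cfg$lead_in
  inh_left <- cfg$n_inhibitory
  pos_left <- cfg$n_trials - cfg$lead_in
  if (.count_completions(pos_left, inh_left, last, run, cfg, memo) == 0)
    stop("unsatisfiable config: no sequence satisfies the run constraints",
         call. = FALSE)
  i <- cfg$lead_in
  while (pos_left > 0L) {
    n_p <- if (!(last == "P" && run >= cfg$max_run_prepotent) &&
               pos_left - 1L >= inh_left) {
      .count_completions(pos_left - 1L, inh_left, "P",
                         if (last == "P") run + 1L else 1L, cfg, memo)
    } else 0
    n_i <- if (inh_left > 0L && !(last == "I" && run >= cfg$max_run_inhibitory)) {
      .count_completions(pos_left - 1L, inh_left - 1L, "I",
                         if (last == "I") run + 1L else 1L, cfg, memo)
    } else 0
    take_inh <- stats::runif(1L) < n_i / (n_p + n_i)
    i <- i + 1L
    if (take_inh) {
      conds[i] <- "inhibitory"
      run <- if (last == "I") run + 1L else 1L
      last <- "I"
      inh_left <- inh_left - 1L
    } else {
      conds[i] <- "prepotent"
      run <- if (last == "P") run + 1L else 1L
      last <- "P"
    }
    pos_left <- pos_left - 1L
  }
  conds
}

#' Generate a constrained pseudo-random trial sequence
#'
#' Draws, for each block, a sequence with exactly `n_inhibitory` inhibitory
#' trials, a forced prepotent lead-in, and no run of consecutive
#' same-condition trials longer than the configured caps. Each block is an
#' independent draw, uniform over all sequences satisfying the constraints;
#' the same seed always reproduces the same sequence.
#'
#' @param config A [block_config()].
#' @param cb One row of [assign_counterbalance()] (or [counterbalance()]):
#'   the participant's prepotent location, which determines where the
#'   smiley appears on each trial.
#' @param seed Integer seed; required for reproducibility.
#' @return A data.frame of class `ecitt_sequence` with columns `block`,
#'   `trial` (both 0-based), `condition` (`"prepotent"`/`"inhibitory"`) and
#'   `smiley_location` (`"top"`/`"bottom"`).
#' @examples
#' cb <- counterbalance("p1", "top")
#' seq <- generate_sequence(block_config(), cb, seed = 1)
#' table(seq$condition)
#' @seealso [validate_sequence()] for checking arbitrary sequences.
#' @export
generate_sequence <- function(config, cb, seed) {
  stopifnot(inherits(config, "block_config"))
  if (!all(c("participant_id", "prepotent_location") %in% names(cb)))
    stop("cb must carry participant_id and prepotent_location",
         call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  blocks <- lapply(seq_len(config$n_blocks) - 1L, function(b) {
    conds <- .sample_block_conditions(config)
    data.frame(
      block = b,
      trial = seq_along(conds) - 1L,
      condition = conds,
      smiley_location = ifelse(conds == "prepotent",
                               cb$prepotent_location,
                               .other_location(cb$prepotent_location)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  attr(out, "config") <- config
  attr(out, "counterbalance") <- cb
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("ecitt_sequence", "data.frame")
  out
}

#' Enumerate all valid block sequences (small configurations)
#'
#' Brute-force enumeration of every condition sequence satisfying a block
#' configuration, intended for small blocks (used e.g. to verify the
#' uniformity of [generate_sequence()]).
#'
#' @param config A [block_config()] with a small number of free positions.
#' @return A character matrix, one row per valid sequence, entries
#'   `"prepotent"`/`"inhibitory"`.
#' @export
enumerate_sequences <- function(config) {
  free <- config$n_trials - config$lead_in
  if (choose(free, config$n_inhibitory) > 1e6)
    stop("configuration too large to enumerate", call. = FALSE)
  base <- rep("prepotent", config$n_trials)
  if (config$n_inhibitory == 0L) {
    seqs <- matrix(base, nrow = 1L)
  } else {
    combos <- utils::combn(free, config$n_inhibitory)
    seqs <- t(apply(combos, 2L, function(pos) {
      s <- base
      s[config$lead_in + pos] <- "inhibitory"
      s
    }))
  }
  ok <- apply(seqs, 1L, function(s) {
    r <- rle(s)
    all(r$lengths[r$values == "prepotent"] <= config$max_run_prepotent) &&
      all(r$lengths[r$values == "inhibitory"] <= config$max_run_inhibitory)
  })
  seqs[ok, , drop = FALSE]
}

#' Validate a trial sequence against a block configuration
#'
#' Checks every generator constraint: per-block inhibitory count, forced
#' prepotent lead-in, and the run caps. Each breach is reported with the
#' block, the trial index where it is detected and the rule it violates.
#'
#' @param seq A data.frame with columns `block`, `trial`, `condition` (as
#'   produced by [generate_sequence()]).
#' @param config A [block_config()].
#' @return A data.frame of violations with columns `block`, `trial`,
#'   `rule`, `detail`; zero rows when the sequence is valid.
#' @export
validate_sequence <- function(seq, config) {
  stopifnot(inherits(config, "block_config"))
  v <- list()
  add <- function(block, trial, rule, detail) {
    v[[length(v) + 1L]] <<- data.frame(
      block = block, trial = trial, rule = rule, detail = detail,
      stringsAsFactors = FALSE)
  }
  blocks <- sort(unique(seq$block))
  if (length(blocks) != config$n_blocks)
    add(NA_integer_, NA_integer_, "n_blocks",
        sprintf("expected %d blocks, found %d", config$n_blocks,
                length(blocks)))
  for (b in blocks) {
    s <- seq[seq$block == b, , drop = FALSE]
    s <- s[order(s$trial), , drop = FALSE]
    conds <- s$condition
    if (length(conds) != config$n_trials)
      add(b, NA_integer_, "n_trials",
          sprintf("expected %d trials, found %d", config$n_trials,
                  length(conds)))
    n_inh <- sum(conds == "inhibitory")
    if (n_inh != config$n_inhibitory)
      add(b, NA_integer_, "n_inhibitory",
          sprintf("expected %d inhibitory trials, found %d",
                  config$n_inhibitory, n_inh))
    if (config$lead_in > 0L) {
      lead <- conds[seq_len(min(config$lead_in, length(conds)))]
      bad <- which(lead != "prepotent")
      if (length(bad))
        add(b, s$trial[bad[1L]], "lead_in",
            sprintf("trial within the first %d must be prepotent",
                    config$lead_in))
    }
    r <- rle(conds)
    ends <- cumsum(r$lengths)
    for (j in seq_along(r$values)) {
      cap <- if (r$values[j] == "prepotent") config$max_run_prepotent
             else config$max_run_inhibitory
      if (r$lengths[j] > cap)
        add(b, s$trial[ends[j] - r$lengths[j] + cap],
            paste0("max_run_", if (r$values[j] == "prepotent")
              "prepotent" else "inhibitory"),
            sprintf("run of %d %s trials exceeds cap %d", r$lengths[j],
                    r$values[j], cap))
    }
  }
  if (length(v) == 0L)
    return(data.frame(block = integer(), trial = integer(),
                      rule = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}

# RNG bookkeeping: seeded operations restore the caller's RNG state
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
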