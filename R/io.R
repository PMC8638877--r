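# Session files: a CSV trial table plus a JSON metadata sidecar
# (<path>.json). Trial numbering is 1-based in files, 0-based in memory;
# times are integer milliseconds end-to-end.

.validity_codes <- c("valid", "invalid_fast", "invalid_finger_at_onset",
                     "invalid_intervention", "invalid_accidental")

#' Write a session to CSV + JSON sidecar
#'
#' The CSV holds the trial table (columns `block`, `trial`, `condition`,
#' `smiley_location`, `touched_location`, `correct`, `rt_ms`, `validity`,
#' `n_touches`) with 1-based block/trial numbering; the header metadata
#' goes to `<path>.json`.
#'
#' @param session An `ecitt_session`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "ecitt_session"))
  tr <- session$trials
  tr$block <- tr$block + 1L
  tr$trial <- tr$trial + 1L
  utils::write.csv(tr, path, row.names = FALSE)
  jsonlite::write_json(session$header, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a session from CSV + JSON sidecar
#'
#' Validates the file on the way in: required columns, known validity
#' codes, non-negative RTs, and (when the header names a variant) the
#' expected block structure. Malformed rows are reported with their
#' 1-based row numbers.
#'
#' @param path CSV file path written by [write_session()].
#' @return An `ecitt_session`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("block", "trial", "condition", "smiley_location",
                "touched_location", "correct", "rt_ms", "validity")
  missing_cols <- setdiff(required, names(tr))
  if (length(missing_cols))
    stop("session file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  problems <- character(0L)
  bad_val <- which(!tr$validity %in% .validity_codes)
  if (length(bad_val))
    problems <- c(problems, sprintf(
      "row %d: unknown validity code '%s'", bad_val, tr$validity[bad_val]))
  bad_rt <- which(!is.na(tr$rt_ms) & tr$rt_ms < 0)
  if (length(bad_rt))
    problems <- c(problems, sprintf("row %d: negative rt_ms", bad_rt))
  bad_cond <- which(!tr$condition %in% c("prepotent", "inhibitory"))
  if (length(bad_cond))
    problems <- c(problems, sprintf("row %d: unknown condition '%s'",
                                    bad_cond, tr$condition[bad_cond]))
  if (length(problems))
    stop("invalid session file:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  header_path <- paste0(path, ".json")
  header <- if (file.exists(header_path)) {
    jsonlite::read_json(header_path, simplifyVector = TRUE)
  } else {
    list(participant_id = "unknown", age_months = NA, visit = 1L,
         variant = NA_character_, counterbalance = NA_character_,
         seed = NA_integer_, software_version = NA_character_)
  }
  tr$block <- as.integer(tr$block) - 1L
  tr$trial <- as.integer(tr$trial) - 1L
  if (!"n_touches" %in% names(tr)) tr$n_touches <- 1L
  if (!is.null(header$variant) && !is.na(header$variant) &&
      header$variant %in% c("ECITT_S1", "ECITT_S2", "ECITT_A")) {
    cfg <- ecitt_variant(header$variant)$config
    blocks <- table(tr$block)
    if (length(blocks) != cfg$n_blocks ||
        any(blocks != cfg$n_trials))
      stop(sprintf(
        "structural error: variant %s expects %d block(s) of %d trials",
        header$variant, cfg$n_blocks, cfg$n_trials), call. = FALSE)
  }
  session <- list(header = header, trials = tr)
  class(session) <- "ecitt_session"
  session
}

#' Export a trial sequence as CSV
#'
#' Columns `block`, `trial` (1-based in the file), `condition`,
#' `smiley_location`.
#'
#' @param seq A [generate_sequence()] output.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  out <- as.data.frame(seq)[, c("block", "trial", "condition",
                                "smiley_location")]
  out$block <- out$block + 1L
  out$trial <- out$trial + 1L
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a score table as CSV
#'
#' @param scores An `ecitt_scores` data.frame (see [score_sessions()]).
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE)
  invisible(path)
}

#' A canned worked-example session
#'
#' A toy toddler session constructed so that, after cleaning (including
#' the first-trial discard), prepotent accuracy is 62.5% and inhibitory
#' accuracy 50%, i.e. AccD = 12.5 and adjusted AccD = 20. Useful as a
#' fixture and as a scoring smoke test.
#'
#' @return An `ecitt_session`.
#' @export
example_session <- function() {
  cb <- counterbalance("example", "top")
  sq <- generate_sequence(block_config(), cb, seed = 42L)
  tr <- sq
  tr <- as.data.frame(tr)
  tr$validity <- "valid"
  tr$correct <- TRUE
  # after discarding trial 1 there remain 23 prepotent and 8 inhibitory
  # valid trials; we need floor-free counts giving 62.5% and 50%, so mark
  # 7 extra prepotent trials invalid (16 valid, 10 correct) and set 4 of 8
  # inhibitory trials incorrect
  prep_idx <- which(tr$condition == "prepotent")[-1L]  # trial 1 discarded
  inh_idx <- which(tr$condition == "inhibitory")
  tr$validity[prep_idx[1:7]] <- "invalid_intervention"
  scored_prep <- setdiff(prep_idx, prep_idx[1:7])
  tr$correct[scored_prep[1:6]] <- FALSE    # 16 valid, 10 correct = 62.5%
  tr$correct[inh_idx[1:4]] <- FALSE        # 8 valid, 4 correct = 50%
  tr$touched_location <- ifelse(tr$correct, tr$smiley_location,
                                .other_location(tr$smiley_location))
  tr$rt_ms <- rep_len(c(900, 1100, 1300, 1500), nrow(tr))
  tr$n_touches <- 1L
  structure(list(
    header = list(participant_id = "example", age_months = 24,
                  visit = 1L, variant = "ECITT_S1",
                  counterbalance = "top", seed = 42L,
                  software_version = as.character(
                    utils::packageVersion("ecitt"))),
    trials = tr[, c("block", "trial", "condition", "smiley_location",
                    "touched_location", "correct", "rt_ms", "validity",
                    "n_touches")]
  ), class = "ecitt_session")
}
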