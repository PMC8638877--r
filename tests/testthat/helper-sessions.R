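# Hand-built session fixtures for scoring tests.

# Build a session from parallel vectors; smiley is at "top" for prepotent
# trials (prepotent location = top).
make_session <- function(conds, correct, rt,
                         validity = "valid", variant = "ECITT_S1") {
  n <- length(conds)
  smiley <- ifelse(conds == "prepotent", "top", "bottom")
  touched <- ifelse(correct, smiley, ifelse(smiley == "top", "bottom",
                                            "top"))
  trials <- data.frame(
    block = rep(0L, n), trial = seq_len(n) - 1L,
    condition = conds, smiley_location = smiley,
    touched_location = touched, correct = correct,
    rt_ms = rt, validity = rep_len(validity, n), n_touches = rep(1L, n),
    stringsAsFactors = FALSE)
  structure(list(
    header = list(participant_id = "t", age_months = NA, visit = 1L,
                  variant = variant, counterbalance = "top",
                  seed = NA_integer_, software_version = "test"),
    trials = trials), class = "ecitt_session")
}

# A toddler session with a leading discardable prepotent trial followed by
# n_prep prepotent trials (k_prep correct) and n_inh inhibitory trials
# (k_inh correct); all RTs valid.
make_counts_session <- function(n_prep, k_prep, n_inh, k_inh, rt = 1000) {
  conds <- c("prepotent",                     # discarded first trial
             rep("prepotent", n_prep), rep("inhibitory", n_inh))
  correct <- c(TRUE,
               rep(c(TRUE, FALSE), c(k_prep, n_prep - k_prep)),
               rep(c(TRUE, FALSE), c(k_inh, n_inh - k_inh)))
  make_session(conds, correct, rep(rt, length(conds)))
}

# Independent brute-force enumeration of valid condition sequences for a
# small block config (oracle; deliberately not the package's DP).
enumerate_oracle <- function(n_trials, n_inh, lead_in, max_p, max_i) {
  free <- n_trials - lead_in
  grids <- rep(list(c("prepotent", "inhibitory")), free)
  all_seqs <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  keys <- character(0L)
  for (r in seq_len(nrow(all_seqs))) {
    s <- c(rep("prepotent", lead_in), unlist(all_seqs[r, ],
                                             use.names = FALSE))
    if (sum(s == "inhibitory") != n_inh) next
    runs <- rle(s)
    if (any(runs$lengths[runs$values == "prepotent"] > max_p)) next
    if (any(runs$lengths[runs$values == "inhibitory"] > max_i)) next
    keys <- c(keys, paste(s, collapse = ","))
  }
  sort(keys)
}

# textbook sums-of-squares oracle for a balanced 2-group x 2-condition
# mixed design
mixed_ss_oracle <- function(d) {
  g <- split(d, d$group)
  grand <- mean(d$y)
  subj_means <- tapply(d$y, d$id, mean)
  subj_groups <- tapply(as.character(d$group), d$id, unique)
  k <- 2                                     # within levels
  ss_between <- k * sum(tapply(subj_means, subj_groups, function(v)
    length(v) * (mean(v) - grand)^2))
  ss_subj_within_grp <- k * sum((subj_means -
    ave(subj_means, subj_groups))^2)
  cond_means <- tapply(d$y, d$cond, mean)
  n_per_cond <- table(d$cond)
  ss_cond <- sum(n_per_cond * (cond_means - grand)^2)
  cell_means <- tapply(d$y, list(d$group, d$cond), mean)
  n_cell <- table(d$group, d$cond)
  ss_cells <- sum(n_cell * (cell_means - grand)^2)
  ss_int <- ss_cells - ss_between - ss_cond
  # residual within: total - subjects - cond - interaction
  ss_total <- sum((d$y - grand)^2)
  ss_resid_within <- ss_total - (ss_between + ss_subj_within_grp) -
    ss_cond - ss_int
  list(between = ss_between, subj = ss_subj_within_grp, cond = ss_cond,
       int = ss_int, resid = ss_resid_within)
}
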