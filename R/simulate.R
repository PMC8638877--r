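# Generative participant models. Correct-trial reaction times follow an
# ex-Gaussian law (Gaussian + exponential), the standard descriptive model
# for right-skewed RT distributions; inhibitory slowing enters as a
# location shift on correct inhibitory trials only.

# ex-Gaussian draws, resampling the rare non-positive values so that
# generated correct-trial RTs are strictly positive
.rexgauss <- function(n, mu, sigma, tau) {
  x <- stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mu, sigma) +
      stats::rexp(length(bad), rate = 1 / tau)
    bad <- bad[x[bad] <= 0]
  }
  x
}

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

#' Generative model of one participant's task behaviour
#'
#' Parameterises how a simulated participant behaves on the touchscreen
#' task: per-condition accuracy, an ex-Gaussian correct-RT distribution
#' with an additive location cost on correct inhibitory responses, and
#' rates of the trial-level events seen in real toddler data (anticipatory
#' touches below the RT validity floor, long distracted responses above
#' the RT ceiling, and externally coded invalid trials such as a finger on
#' the screen at trial onset or caregiver intervention).
#'
#' @param p_correct_prepotent,p_correct_inhibitory Probability of a correct
#'   first touch per condition.
#' @param rt_prepotent Named numeric vector `c(mu, sigma, tau)` in ms: the
#'   ex-Gaussian parameters of correct prepotent RTs.
#' @param inhibitory_cost_ms Added to `mu` on correct inhibitory trials.
#' @param p_anticipation Probability that a trial is an anticipatory touch
#'   (RT below the variant's floor; coded `invalid_fast`).
#' @param p_distraction Probability that a (valid) trial's RT exceeds the
#'   variant's ceiling (the trial stays valid but is dropped from RT
#'   analyses).
#' @param p_invalid Probability of an externally coded invalid trial
#'   (finger at onset / intervention / accidental touch).
#' @return An object of class `participant_model`.
#' @examples
#' participant_model(0.95, 0.63)
#' @export
participant_model <- function(p_correct_prepotent,
                              p_correct_inhibitory,
                              rt_prepotent = c(mu = 1300, sigma = 250,
                                               tau = 400),
                              inhibitory_cost_ms = 200,
                              p_anticipation = 0,
                              p_distraction = 0,
                              p_invalid = 0) {
  probs <- c(p_correct_prepotent, p_correct_inhibitory,
             p_anticipation, p_distraction, p_invalid)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  rt <- rt_prepotent
  if (!all(c("mu", "sigma", "tau") %in% names(rt)))
    stop("rt_prepotent needs named components mu, sigma, tau",
         call. = FALSE)
  if (rt[["sigma"]] <= 0 || rt[["tau"]] <= 0)
    stop("sigma and tau must be positive", call. = FALSE)
  structure(list(
    p_correct_prepotent = p_correct_prepotent,
    p_correct_inhibitory = p_correct_inhibitory,
    rt_prepotent = rt[c("mu", "sigma", "tau")],
    inhibitory_cost_ms = inhibitory_cost_ms,
    p_anticipation = p_anticipation,
    p_distraction = p_distraction,
    p_invalid = p_invalid
  ), class = "participant_model")
}

#' Library of age-profile presets
#'
#' Group-level behaviour presets spanning toddlerhood to older adulthood.
#' Toddler accuracies follow the reported group pattern (inhibitory
#' accuracy rising from about 63% at 18 months to 89% at 24 months and 92%
#' at 30 months while prepotent accuracy stays above 90%); child and adult
#' presets are near ceiling on accuracy with condition effects carried
#' mainly by reaction time. `between_subject_sd` gives the dispersion of
#' individual parameters around the preset: Gaussian on logit(accuracy)
#' and on log of the RT location parameter.
#'
#' @param label Optional profile label; if supplied, only that profile is
#'   returned.
#' @return A named list of profiles (or a single profile), each a list
#'   with `label`, `age_months`, `model` (a [participant_model()]) and
#'   `between_subject_sd` (`logit_acc`, `log_mu`).
#' @export
age_profiles <- function(label = NULL) {
  mk <- function(label, age_months, p_prep, p_inh, mu, sigma, tau, cost,
                 p_ant, p_dis, p_inv, sd_logit, sd_logmu) {
    list(label = label, age_months = age_months,
         model = participant_model(
           p_correct_prepotent = p_prep, p_correct_inhibitory = p_inh,
           rt_prepotent = c(mu = mu, sigma = sigma, tau = tau),
           inhibitory_cost_ms = cost, p_anticipation = p_ant,
           p_distraction = p_dis, p_invalid = p_inv),
         between_subject_sd = list(logit_acc = sd_logit, log_mu = sd_logmu))
  }
  lib <- list(
    `18m` = mk("18m", 18, 0.93, 0.63, 1350, 280, 450, 220,
               0.06, 0.05, 0.05, 0.9, 0.15),
    `21m` = mk("21m", 21, 0.93, 0.76, 1300, 270, 430, 210,
               0.05, 0.05, 0.05, 0.9, 0.15),
    `24m` = mk("24m", 24, 0.94, 0.89, 1250, 260, 420, 200,
               0.05, 0.04, 0.04, 0.9, 0.15),
    `30m` = mk("30m", 30, 0.95, 0.92, 1150, 240, 400, 190,
               0.04, 0.03, 0.04, 0.9, 0.12),
    child = mk("child", 95, 0.998, 0.943, 640, 90, 140, 100,
               0.01, 0.002, 0, 0.7, 0.10),
    young_adult = mk("young_adult", 275, 0.999, 0.995, 470, 60, 110, 57,
                     0.002, 0, 0, 0.5, 0.08),
    older_adult = mk("older_adult", 835, 0.999, 0.982, 620, 80, 130, 95,
                     0.002, 0, 0, 0.6, 0.08)
  )
  if (is.null(label)) return(lib)
  if (!label %in% names(lib))
    stop(sprintf("unknown profile '%s'", label), call. = FALSE)
  lib[[label]]
}

# draw validity code, touch and RT for one trial; returns a list
.simulate_trial <- function(cond, smiley, prepotent_loc, variant, model) {
  other <- .other_location(smiley)
  u <- stats::runif(3L)
  if (u[1L] < model$p_invalid) {
    validity <- sample(c("invalid_finger_at_onset", "invalid_intervention",
                         "invalid_accidental"), 1L)
    touched <- sample(c("top", "bottom"), 1L)
    rt <- round(stats::runif(1L, variant$rt_floor_ms, 3000))
    return(list(validity = validity, touched = touched, rt = rt,
                correct = touched == smiley, n_touches = 1L))
  }
  if (u[2L] < model$p_anticipation) {
    # anticipatory tap, almost always at the prepotent location
    touched <- if (stats::runif(1L) < 0.9) prepotent_loc else other
    rt <- round(stats::runif(1L, 50, variant$rt_floor_ms - 1))
    return(list(validity = "invalid_fast", touched = touched, rt = rt,
                correct = touched == smiley, n_touches = 1L))
  }
  p_ok <- if (cond == "prepotent") model$p_correct_prepotent
          else model$p_correct_inhibitory
  correct <- u[3L] < p_ok
  mu <- model$rt_prepotent[["mu"]] +
    if (cond == "inhibitory" && correct) model$inhibitory_cost_ms else 0
  rt <- .rexgauss(1L, mu, model$rt_prepotent[["sigma"]],
                  model$rt_prepotent[["tau"]])
  if (stats::runif(1L) < model$p_distraction)
    rt <- stats::runif(1L, variant$rt_ceiling_ms + 200,
                       variant$rt_ceiling_ms + 4000)
  rt <- max(round(rt), variant$rt_floor_ms)  # valid trials sit above floor
  touched <- if (correct) smiley else .other_location(smiley)
  n_touches <- 1L
  if (variant$incorrect_behavior == "unresponsive" && !correct)
    n_touches <- 2L  # the trial only ends on the later corrective touch
  list(validity = "valid", touched = touched, rt = rt, correct = correct,
       n_touches = n_touches)
}

#' Simulate one session from a trial sequence
#'
#' Plays a [participant_model()] through a generated trial sequence under
#' a task variant, producing a trial-level session log in the same form as
#' coded real data. In the unresponsive variant (`ECITT_S2`) an incorrect
#' first touch is followed by a corrective touch, and scoring fields
#' (accuracy, RT) reflect the first touch.
#'
#' @param seq An [generate_sequence()] output (or any data.frame with
#'   columns `block`, `trial`, `condition`, `smiley_location`).
#' @param variant An [ecitt_variant()].
#' @param model A [participant_model()].
#' @param seed Optional integer seed.
#' @param participant_id,age_months,visit Session metadata.
#' @return An object of class `ecitt_session`: a list with `header`
#'   (metadata) and `trials` (the trial table with columns `block`,
#'   `trial`, `condition`, `smiley_location`, `touched_location`,
#'   `correct`, `rt_ms`, `validity`, `n_touches`).
#' @examples
#' cb <- counterbalance("p1", "top")
#' v <- ecitt_variant("ECITT_S1")
#' s <- generate_sequence(v$config, cb, seed = 1)
#' sess <- simulate_session(s, v, age_profiles("24m")$model, seed = 2)
#' head(sess$trials)
#' @export
simulate_session <- function(seq, variant, model, seed = NULL,
                             participant_id = "sim", age_months = NA,
                             visit = 1L) {
  stopifnot(inherits(variant, "ecitt_variant"),
            inherits(model, "participant_model"))
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
  }
  cb <- attr(seq, "counterbalance")
  prepotent_loc <- if (!is.null(cb)) cb$prepotent_location else {
    # recover the prepotent side from the sequence itself
    with(seq, names(sort(table(smiley_location[condition == "prepotent"]),
                         decreasing = TRUE)))[1L]
  }
  n <- nrow(seq)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- .simulate_trial(seq$condition[i], seq$smiley_location[i],
                                prepotent_loc, variant, model)
  }
  trials <- data.frame(
    block = seq$block,
    trial = seq$trial,
    condition = seq$condition,
    smiley_location = seq$smiley_location,
    touched_location = vapply(out, `[[`, character(1L), "touched"),
    correct = vapply(out, `[[`, logical(1L), "correct"),
    rt_ms = vapply(out, function(t) as.numeric(t$rt), numeric(1L)),
    validity = vapply(out, `[[`, character(1L), "validity"),
    n_touches = vapply(out, `[[`, integer(1L), "n_touches"),
    stringsAsFactors = FALSE
  )
  structure(list(
    header = list(participant_id = participant_id,
                  age_months = age_months,
                  visit = as.integer(visit),
                  variant = variant$name,
                  counterbalance = prepotent_loc,
                  seed = if (is.null(seed)) NA_integer_
                         else as.integer(seed),
                  software_version = as.character(
                    utils::packageVersion("ecitt"))),
    trials = trials
  ), class = "ecitt_session")
}

#' @export
print.ecitt_session <- function(x, ...) {
  cat(sprintf("<ecitt_session> %s, visit %d, %s, %d trials\n",
              x$header$participant_id, x$header$visit, x$header$variant,
              nrow(x$trials)))
  invisible(x)
}

# Solve for the logit intercept b such that E[inv_logit(b + sd * Z)]
# equals the target group-mean accuracy (Z standard normal). Keeps the
# profile presets interpretable as group means under heterogeneity.
.solve_logit_intercept <- function(target, sd) {
  target <- min(max(target, 1e-4), 1 - 1e-4)
  if (sd <= 0) return(.logit(target))
  z <- seq(-6, 6, length.out = 241L)
  w <- stats::dnorm(z); w <- w / sum(w)
  f <- function(b) sum(w * .inv_logit(b + sd * z)) - target
  stats::uniroot(f, c(-25, 25), tol = 1e-9)$root
}

# participant-specific parameter draw around a profile preset
.individualise <- function(profile, z_acc_inh, z_acc_prep, z_mu) {
  m <- profile$model
  sdl <- profile$between_subject_sd$logit_acc
  sdm <- profile$between_subject_sd$log_mu
  clamp <- function(p) min(max(p, 1e-4), 1 - 1e-4)
  participant_model(
    p_correct_prepotent = clamp(.inv_logit(
      .solve_logit_intercept(m$p_correct_prepotent, sdl) +
        sdl * z_acc_prep)),
    p_correct_inhibitory = clamp(.inv_logit(
      .solve_logit_intercept(m$p_correct_inhibitory, sdl) +
        sdl * z_acc_inh)),
    rt_prepotent = c(mu = m$rt_prepotent[["mu"]] * exp(sdm * z_mu),
                     sigma = m$rt_prepotent[["sigma"]],
                     tau = m$rt_prepotent[["tau"]]),
    inhibitory_cost_ms = m$inhibitory_cost_ms,
    p_anticipation = m$p_anticipation,
    p_distraction = m$p_distraction,
    p_invalid = m$p_invalid
  )
}

#' Simulate a cohort of sessions
#'
#' Cross-sectional design: `n_per_profile` independent participants per
#' profile, one session each. Longitudinal design: `n_per_profile`
#' participants, each tested once per profile in order (the profiles act
#' as the visit schedule, e.g. 18m / 21m / 24m); each participant's
#' inhibitory-accuracy parameter is driven by latent traits that are
#' equicorrelated across visits with correlation `stability_r`, so that
#' score-stability recovery can be tested against a known ground truth.
#' Prepotent accuracy and RT speed perturbations are stable traits shared
#' across a participant's visits.
#'
#' @param profiles List of profiles from [age_profiles()].
#' @param n_per_profile Participants per profile (cross-sectional) or the
#'   number of longitudinal participants.
#' @param design `"cross_sectional"` or `"longitudinal"`.
#' @param stability_r Cross-visit correlation of the latent inhibition
#'   trait (longitudinal design only); must keep the equicorrelation
#'   matrix positive definite.
#' @param variant An [ecitt_variant()]; defaults to the toddler variant.
#' @param seed Master seed; per-participant substreams are derived from it
#'   deterministically.
#' @return A list of [simulate_session()] objects, each with
#'   `participant_id` and `visit` filled in.
#' @export
simulate_cohort <- function(profiles, n_per_profile,
                            design = c("cross_sectional", "longitudinal"),
                            stability_r = 0,
                            variant = ecitt_variant("ECITT_S1"),
                            seed = 1L) {
  design <- match.arg(design)
  if (n_per_profile < 2L) stop("n_per_profile must be at least 2",
                               call. = FALSE)
  if (!is.finite(stability_r) || stability_r < -1 || stability_r > 1)
    stop("stability_r must lie in [-1, 1]", call. = FALSE)
  if (!is.null(profiles$model)) profiles <- list(profiles)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  sessions <- list()
  if (design == "cross_sectional") {
    pid <- 0L
    for (pf in profiles) {
      for (i in seq_len(n_per_profile)) {
        pid <- pid + 1L
        z <- stats::rnorm(3L)
        model <- .individualise(pf, z[1L], z[2L], z[3L])
        cb <- counterbalance(sprintf("p%03d", pid),
                             if (pid %% 2L == 1L) "top" else "bottom")
        sseed <- (as.integer(seed) + 7919L * pid) %% .Machine$integer.max
        sq <- generate_sequence(variant$config, cb, seed = sseed)
        sessions[[length(sessions) + 1L]] <- simulate_session(
          sq, variant, model, seed = sseed + 1L,
          participant_id = cb$participant_id,
          age_months = pf$age_months, visit = 1L)
      }
    }
  } else {
    v <- length(profiles)
    # equicorrelated latent traits across visits; eigen square root so
    # that the boundary cases (r = 1, r = -1/(v-1)) are admissible
    sigma <- matrix(stability_r, v, v); diag(sigma) <- 1
    ei <- eigen(sigma, symmetric = TRUE)
    if (any(ei$values < -1e-8))
      stop("stability_r does not give a positive semi-definite ",
           "cross-visit correlation matrix", call. = FALSE)
    rt_sigma <- ei$vectors %*% diag(sqrt(pmax(ei$values, 0)), v)
    for (i in seq_len(n_per_profile)) {
      z_inh <- as.numeric(rt_sigma %*% stats::rnorm(v))
      z_prep <- stats::rnorm(1L)  # stable traits across visits
      z_mu <- stats::rnorm(1L)
      cb <- counterbalance(sprintf("p%03d", i),
                           if (i %% 2L == 1L) "top" else "bottom")
      for (j in seq_len(v)) {
        model <- .individualise(profiles[[j]], z_inh[j], z_prep, z_mu)
        sseed <- (as.integer(seed) + 7919L * i + 104729L * j) %%
          .Machine$integer.max
        sq <- generate_sequence(variant$config, cb, seed = sseed)
        sessions[[length(sessions) + 1L]] <- simulate_session(
          sq, variant, model, seed = sseed + 1L,
          participant_id = cb$participant_id,
          age_months = profiles[[j]]$age_months, visit = j)
      }
    }
  }
  sessions
}
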