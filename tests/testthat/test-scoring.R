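v_s1 <- ecitt_variant("ECITT_S1")

test_that("cleaning applies validity codes, RT windows and first-trial discard", {
  # a 250 ms toddler trial is invalid and enters neither set
  s <- make_session(c("prepotent", "prepotent", "inhibitory"),
                    c(TRUE, TRUE, TRUE), c(1000, 250, 1200))
  sets <- clean_trials(s, v_s1)
  expect_false(250 %in% sets$accuracy_set$rt_ms)
  expect_false(250 %in% sets$rt_set$rt_ms)
  # a valid correct 5200 ms trial counts for accuracy but not RT
  s2 <- make_session(rep("prepotent", 3), rep(TRUE, 3),
                     c(1000, 5200, 900))
  sets2 <- clean_trials(s2, v_s1)
  expect_true(5200 %in% sets2$accuracy_set$rt_ms)
  expect_false(5200 %in% sets2$rt_set$rt_ms)
  # incorrect trials stay in the accuracy set but never the RT set
  s3 <- make_session(rep("prepotent", 3), c(TRUE, FALSE, TRUE),
                     c(1000, 1000, 900))
  expect_equal(nrow(clean_trials(s3, v_s1)$rt_set), 1L)  # first discarded
  # first trial discarded for toddler variants, kept for the adult variant
  s4 <- make_session(rep("prepotent", 4), rep(TRUE, 4), rep(1000, 4))
  expect_equal(nrow(clean_trials(s4, v_s1)$accuracy_set), 3L)
  s4$header$variant <- "ECITT_A"
  expect_equal(nrow(clean_trials(s4, ecitt_variant("ECITT_A"))$accuracy_set),
               4L)
  # empty session gives two empty sets
  s5 <- make_session(character(0), logical(0), numeric(0))
  sets5 <- clean_trials(s5, v_s1)
  expect_equal(nrow(sets5$accuracy_set), 0L)
  expect_equal(nrow(sets5$rt_set), 0L)
})

test_that("condition summaries use exact percentages and the even-median rule", {
  s <- make_counts_session(24, 18, 8, 4)
  sets <- clean_trials(s, v_s1)
  sm <- summarize_conditions(sets$accuracy_set, sets$rt_set)
  expect_equal(sm$pct_correct[sm$condition == "prepotent"], 75)
  # median of an even count is the mean of the two central values
  s2 <- make_session(c("inhibitory", "inhibitory"), c(TRUE, TRUE),
                     c(400, 600), variant = "ECITT_A")
  sm2 <- summarize_conditions(clean_trials(s2,
                                           ecitt_variant("ECITT_A"))$accuracy_set,
                              clean_trials(s2,
                                           ecitt_variant("ECITT_A"))$rt_set)
  expect_equal(sm2$median_rt_ms[sm2$condition == "inhibitory"], 500)
  # all inhibitory trials incorrect: median undefined, RTD undefined
  s3 <- make_counts_session(10, 10, 4, 0)
  sets3 <- clean_trials(s3, v_s1)
  sm3 <- summarize_conditions(sets3$accuracy_set, sets3$rt_set)
  expect_true(is.na(sm3$median_rt_ms[sm3$condition == "inhibitory"]))
  sc3 <- inhibition_scores(sm3)
  expect_true(is.na(sc3$rtd_ms))
  expect_equal(sc3$accd, 100)
})

test_that("worked AccD examples score exactly", {
  # 62.5% prepotent vs 50% inhibitory
  s <- make_counts_session(16, 10, 8, 4)
  sc <- score_session(s)
  expect_equal(sc$accd, 12.5)
  expect_equal(sc$accd_adjusted, 20)
  expect_true(sc$included)
  # 100% prepotent vs 87.5% inhibitory gives the same AccD
  s2 <- make_counts_session(16, 16, 8, 7)
  sc2 <- score_session(s2)
  expect_equal(sc2$accd, 12.5)
  expect_equal(sc2$accd_adjusted, 12.5)
  # the shipped fixture encodes the first example
  expect_equal(score_session(example_session())$accd, 12.5)
})

test_that("inclusion threshold is strictly greater than 60%", {
  # exactly 60% prepotent -> excluded
  s60 <- make_counts_session(20, 12, 8, 4)
  sc60 <- score_session(s60)
  expect_false(sc60$included)
  expect_match(sc60$exclusion_reason, "60%")
  # just above -> included
  s61 <- make_counts_session(20, 13, 8, 4)
  expect_true(score_session(s61)$included)
  # excluded sessions still return scores
  expect_false(is.na(sc60$accd))
})

test_that("scores are invariant to adding invalid-coded trials", {
  base <- make_counts_session(16, 10, 8, 4)
  sc <- score_session(base)
  for (code in c("invalid_fast", "invalid_finger_at_onset",
                 "invalid_intervention", "invalid_accidental")) {
    extra <- base
    add <- make_session(c("prepotent", "inhibitory"), c(FALSE, TRUE),
                        if (code == "invalid_fast") c(100, 150)
                        else c(700, 900),
                        validity = code)$trials
    add$trial <- max(extra$trials$trial) + 1:2
    extra$trials <- rbind(extra$trials, add)
    sc2 <- score_session(extra)
    expect_equal(sc2$accd, sc$accd)
    expect_equal(sc2$accd_adjusted, sc$accd_adjusted)
    expect_equal(sc2$rtd_ms, sc$rtd_ms)
  }
})

test_that("score identities and robustness properties hold", {
  # equal condition accuracies give AccD 0; perfect session gives 0/0/defined RTD
  eq <- make_counts_session(16, 12, 8, 6)   # both 75%
  expect_equal(score_session(eq)$accd, 0)
  perfect <- make_counts_session(16, 16, 8, 8)
  scp <- score_session(perfect)
  expect_equal(scp$accd, 0)
  expect_equal(scp$accd_adjusted, 0)
  expect_false(is.na(scp$rtd_ms))
  # adjusted AccD >= AccD whenever AccD > 0 and prepotent < 100%
  set.seed(11)
  for (i in 1:20) {
    kp <- sample(10:15, 1); ki <- sample(0:5, 1)
    sc <- score_session(make_counts_session(16, kp, 8, ki))
    if (!is.na(sc$accd) && sc$accd > 0 && sc$prepotent_pct_correct < 100)
      expect_gte(sc$accd_adjusted, sc$accd)
  }
  # median RT unchanged by perturbing an RT strictly above the median
  s <- make_counts_session(16, 16, 8, 8, rt = 1000)
  s$trials$rt_ms <- 500 + 100 * seq_len(nrow(s$trials))
  before <- score_session(s)
  idx <- which.max(s$trials$rt_ms)
  s$trials$rt_ms[idx] <- s$trials$rt_ms[idx] + 1500
  after <- score_session(s)
  expect_equal(after$prepotent_median_rt_ms, before$prepotent_median_rt_ms)
})

test_that("outlier flagging marks extreme scores without removing them", {
  sc <- data.frame(rtd_ms = c(rnorm(20, 100, 20), 2025))
  flagged <- flag_outliers(sc)
  expect_equal(nrow(flagged), 21L)
  expect_true(flagged$outlier[21L])
  expect_false(any(flagged$outlier[1:20]))
})
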