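test_that("cronbach alpha matches its covariance-form oracle and limits", {
  # identical items with variance -> alpha = 1
  col <- c(1, 0, 1, 1, 0)
  expect_equal(cronbach_alpha(cbind(col, col, col)), 1)
  # hand matrix against the covariance-form oracle
  m <- matrix(c(1, 0, 1,
                1, 1, 1,
                0, 0, 1,
                0, 1, 0), nrow = 4L, byrow = TRUE)
  C <- stats::cov(m)
  oracle <- ncol(m) / (ncol(m) - 1) * (1 - sum(diag(C)) / sum(C))
  expect_equal(cronbach_alpha(m), oracle)
  # independent items -> alpha near 0
  set.seed(101)
  big <- matrix(rbinom(4000, 1, 0.5), ncol = 8L)
  expect_lt(abs(cronbach_alpha(big)), 0.15)
  # item relabeling invariance
  expect_equal(cronbach_alpha(m[, c(3, 1, 2)]), cronbach_alpha(m))
  # degenerate inputs are errors, not NaN
  expect_error(cronbach_alpha(matrix(1, 4, 3)), "variance")
  # rows with missing items are dropped (complete-trials rule)
  m_na <- rbind(m, c(1, NA, 1))
  expect_equal(cronbach_alpha(m_na), cronbach_alpha(m))
})

test_that("cohens kappa matches hand computation and is symmetric", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  # 2x2 hand table: 20 trials, agreement 17, margins 12/8 vs 11/9
  r1 <- rep(c("v", "i"), c(12, 8))
  r2 <- c(rep("v", 10), "i", "i", rep("i", 7), "v")
  tab <- table(r1, r2) / 20
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  expect_equal(cohens_kappa(r1, r2), (p_o - p_e) / (1 - p_e))
  expect_equal(cohens_kappa(r2, r1), cohens_kappa(r1, r2))
  # independent raters -> kappa near 0
  set.seed(7)
  a <- sample(c("x", "y"), 4000, TRUE)
  b <- sample(c("x", "y"), 4000, TRUE)
  expect_lt(abs(cohens_kappa(a, b)), 0.05)
  expect_error(cohens_kappa("a", c("a", "b")), "equal length")
})

test_that("welch t agrees with the base oracle and reduces to student t", {
  set.seed(21)
  x <- rnorm(14, 10, 3); y <- rnorm(20, 8, 6)
  got <- welch_t(x, y)
  ref <- stats::t.test(x, y)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$df, unname(ref$parameter))
  expect_equal(got$p, ref$p.value)
  expect_equal(got$ci, as.numeric(ref$conf.int), tolerance = 1e-10)
  # identical groups -> t = 0, d = 0
  z <- welch_t(x, x)
  expect_equal(z$t, 0)
  expect_equal(z$d, 0)
  # equal variances and sizes: Welch df equals Student df and t matches
  y2 <- x + 5
  red <- welch_t(x, y2)
  stu <- stats::t.test(x, y2, var.equal = TRUE)
  expect_equal(red$df, length(x) + length(y2) - 2)
  expect_equal(red$t, unname(stu$statistic))
})

test_that("effect-size conventions reproduce raw-data identities", {
  set.seed(22)
  x <- rnorm(12, 5, 2); y <- x + rnorm(12, 1, 1)
  got <- paired_t(x, y)
  # reduction oracle: one-sample t on the differences
  ref <- stats::t.test(x - y)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  expect_equal(got$d, got$t / sqrt(12))  # paired d convention
  # summary-statistic input path
  s <- welch_t(list(mean = mean(x), sd = sd(x), n = length(x)),
               list(mean = mean(y), sd = sd(y), n = length(y)))
  raw <- welch_t(x, y)
  expect_equal(s$t, raw$t)
  expect_equal(s$d, raw$d)
})


test_that("mixed anova matches a brute-force sums-of-squares oracle", {
  set.seed(31)
  n <- 8L
  d <- expand.grid(id = paste0("s", 1:(2 * n)),
                   cond = c("prepotent", "inhibitory"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("s", "", d$id)) <= n, "g24", "g30")
  d$y <- rnorm(nrow(d), 70, 10) + ifelse(d$cond == "inhibitory", -8, 0) +
    ifelse(d$group == "g30", 5, 0)
  res <- mixed_anova(d, dv = "y", subject = "id", within = "cond",
                     between = "group")
  o <- mixed_ss_oracle(d)
  f_between <- (o$between / 1) / (o$subj / (2 * n - 2))
  f_cond <- (o$cond / 1) / (o$resid / (2 * n - 2))
  f_int <- (o$int / 1) / (o$resid / (2 * n - 2))
  expect_equal(res$F[res$effect == "group"], f_between)
  expect_equal(res$F[res$effect == "cond"], f_cond)
  expect_equal(res$F[res$effect == "group:cond"], f_int)
  expect_equal(res$pes[res$effect == "group"],
               o$between / (o$between + o$subj))
  expect_equal(res$pes[res$effect == "cond"], o$cond / (o$cond + o$resid))
  expect_true(all(res$pes >= 0 & res$pes <= 1))
})

test_that("between-only effect reduces to squared student t on subject means", {
  set.seed(32)
  n <- 10L
  d <- expand.grid(id = paste0("s", 1:(2 * n)),
                   cond = c("a", "b"), stringsAsFactors = FALSE)
  d$group <- rep(c("g1", "g2"), each = n)[match(d$id,
                                                paste0("s", 1:(2 * n)))]
  d$y <- rnorm(nrow(d)) + ifelse(d$group == "g2", 1.5, 0)
  res <- mixed_anova(d, "y", "id", within = "cond", between = "group")
  sm <- tapply(d$y, d$id, mean)
  sg <- tapply(as.character(d$group), d$id, unique)
  t_stu <- stats::t.test(sm[sg == "g1"], sm[sg == "g2"],
                         var.equal = TRUE)$statistic
  expect_equal(res$F[res$effect == "group"], unname(t_stu)^2)
})

test_that("fully-within two-factor anova runs with listwise deletion", {
  set.seed(33)
  d <- expand.grid(id = paste0("s", 1:12),
                   age = c("18m", "21m", "24m"),
                   cond = c("prepotent", "inhibitory"),
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d), 80, 8) +
    ifelse(d$cond == "inhibitory", -10, 0) +
    (as.integer(factor(d$age)) - 1) * 3
  # knock out one cell of one participant: that participant is dropped
  d2 <- d[!(d$id == "s1" & d$age == "18m" & d$cond == "inhibitory"), ]
  res <- mixed_anova(d2, "y", "id", within = c("age", "cond"))
  expect_equal(attr(res, "dropped"), "s1")
  expect_equal(attr(res, "n_subjects"), 11L)
  expect_setequal(res$effect, c("age", "cond", "age:cond"))
  expect_true(all(is.finite(res$F)))
  expect_true(all(res$pes >= 0 & res$pes <= 1))
  # null data: all F small
  d$y <- rnorm(nrow(d))
  res0 <- mixed_anova(d, "y", "id", within = c("age", "cond"))
  expect_true(all(res0$p > 1e-4))
})

test_that("correlation and bootstrap CI behave and reproduce", {
  set.seed(41)
  x <- rnorm(30); y <- 0.6 * x + rnorm(30, 0, 0.8)
  r1 <- correlate(x, y, B = 500, seed = 5)
  r2 <- correlate(x, y, B = 500, seed = 5)
  expect_identical(r1$ci_low, r2$ci_low)     # bit-reproducible
  expect_equal(r1$r, stats::cor(x, y))
  expect_equal(r1$p, stats::cor.test(x, y)$p.value)
  expect_true(r1$ci_low <= r1$r && r1$r <= r1$ci_high)
  # y = x degenerate: r = 1, CI handled
  rd <- correlate(x, x, B = 100, seed = 1)
  expect_equal(rd$r, 1)
  expect_error(correlate(rep(1, 10), rnorm(10)), "variance")
})

test_that("partial correlation matches the first-order recursive formula", {
  # 10-point hand dataset with one control
  x <- c(2.1, 3.4, 1.8, 5.0, 4.2, 3.3, 2.7, 4.8, 3.9, 1.2)
  y <- c(1.0, 2.2, 1.5, 4.1, 3.0, 2.9, 2.0, 4.4, 3.1, 0.7)
  z <- c(0.5, 1.1, 0.2, 2.0, 1.8, 1.2, 0.9, 2.2, 1.5, 0.1)
  got <- partial_correlate(x, y, z, B = 200, seed = 3)
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
  oracle <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  expect_equal(got$r, oracle)
  # control uncorrelated with both -> partial r ~ raw r
  set.seed(42)
  x2 <- rnorm(200); y2 <- 0.5 * x2 + rnorm(200)
  z2 <- rnorm(200)
  expect_lt(abs(partial_correlate(x2, y2, z2, B = 50, seed = 1)$r -
                  cor(x2, y2)), 0.05)
})

test_that("bootstrap CI coverage is near nominal on bivariate normal data", {
  set.seed(55)
  rho <- 0.5; n <- 40L
  cover <- vapply(seq_len(500L), function(i) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    ci <- correlate(x, y, B = 199, seed = i)
    ci$ci_low <= rho && rho <= ci$ci_high
  }, logical(1L))
  expect_gt(mean(cover), 0.89)   # percentile bootstrap undercovers a little
  expect_lt(mean(cover), 0.99)
})

test_that("age-trend comparison identifies linear and quadratic shapes", {
  # exactly linear data: quadratic increment ~ 0
  age <- seq(18, 30, by = 1)
  lin <- suppressWarnings(age_trend(age, 100 - 2 * age))  # exact fit
  expect_lt(lin$delta_r2, 1e-10)
  # u-shaped lifespan data: significant quadratic increment and
  # coefficients matching the normal-equations oracle
  set.seed(61)
  a <- runif(80, 5, 80)
  y <- 30 - 1.2 * a + 0.015 * a^2 + rnorm(80, 0, 2)
  tr <- age_trend(a, y)
  expect_lt(tr$p, 0.01)
  X <- cbind(1, a, a^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(coef(tr$quadratic)), as.numeric(beta),
               tolerance = 1e-8)
  expect_error(age_trend(rep(2, 10), rnorm(10)), "degenerate")
})

test_that("toddler-only simulated cohort shows a negative accd age slope", {
  profs <- age_profiles()[c("18m", "21m", "24m", "30m")]
  sessions <- simulate_cohort(profs, 30, "cross_sectional", seed = 71)
  sc <- score_sessions(sessions)
  sc <- sc[sc$included, ]
  tr <- age_trend(sc$age_months, sc$accd)
  expect_lt(coef(tr$linear)[["age"]], 0)
})
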