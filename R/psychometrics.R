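# Internal consistency, agreement, and the validation statistics.
# Conventions: sample (n-1) variances throughout; two-tailed p-values;
# pooled-SD Cohen's d for independent groups; paired d = t / sqrt(n);
# percentile bootstrap with B = 1000 seeded resamples of participants.

#' Cronbach's alpha for an item (trial) matrix
#'
#' \eqn{\alpha = k/(k-1) (1 - \sum_j s_j^2 / s_{total}^2)} with sample
#' variances, computed over participants with complete responses on all
#' `k` items (rows with any missing entry are dropped, mirroring the
#' complete-trials inclusion rule used for internal-consistency analyses
#' of inhibitory trial accuracy).
#'
#' @param m Numeric matrix or data.frame, participants x items (binary
#'   accuracy or RT).
#' @return Alpha as a single number.
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 complete participants and 2 items",
         call. = FALSE)
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0)
    stop("total-score variance is zero; alpha undefined", call. = FALSE)
  item_var <- sum(apply(m, 2L, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' Cohen's kappa between two coders
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} between
#' two equal-length label sequences (e.g. two coders' validity or
#' accuracy codes for the same trials).
#'
#' @param r1,r2 Label vectors of equal length.
#' @return Kappa as a single number.
#' @export
cohens_kappa <- function(r1, r2) {
  if (length(r1) != length(r2))
    stop("label sequences must have equal length", call. = FALSE)
  r1 <- as.character(r1); r2 <- as.character(r2)
  lev <- sort(unique(c(r1, r2)))
  if (length(lev) < 2L)
    stop("need at least 2 observed categories", call. = FALSE)
  tab <- table(factor(r1, lev), factor(r2, lev)) / length(r1)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (1 - p_e == 0)
    stop("chance agreement is 1; kappa undefined", call. = FALSE)
  (p_o - p_e) / (1 - p_e)
}

.ttest_result <- function(t, df, p, d, mean_diff, ci = c(NA, NA),
                          type = "welch") {
  structure(list(t = t, df = df, p = p, d = d, mean_diff = mean_diff,
                 ci = ci, type = type), class = "ecitt_ttest")
}

#' @export
print.ecitt_ttest <- function(x, ...) {
  cat(sprintf("%s t(%s) = %.2f, p = %.4g, d = %.2f, mean diff = %.3g\n",
              x$type, format(round(x$df, 2L)), x$t, x$p, x$d, x$mean_diff))
  invisible(x)
}

#' Welch's t test with pooled-SD effect size
#'
#' Two-sample t test with the Welch-Satterthwaite degrees of freedom and a
#' pooled-SD Cohen's d, accepting either raw group vectors or `(mean, sd,
#' n)` summary lists so that printed group statistics can be re-analysed
#' directly.
#'
#' @param x,y Numeric vectors, or lists/named vectors with elements
#'   `mean`, `sd`, `n`.
#' @return An object of class `ecitt_ttest` with `t`, `df`, two-tailed
#'   `p`, pooled-SD `d`, `mean_diff` and an analytic 95% CI for the mean
#'   difference.
#' @examples
#' welch_t(list(mean = 19.29, sd = 29.72, n = 36),
#'         list(mean = 5.37, sd = 10.64, n = 41))
#' @export
welch_t <- function(x, y) {
  as_stats <- function(g) {
    if (is.list(g) || (!is.null(names(g)) && all(c("mean", "sd", "n")
                                                 %in% names(g)))) {
      list(m = as.numeric(g[["mean"]]), s = as.numeric(g[["sd"]]),
           n = as.numeric(g[["n"]]))
    } else {
      g <- g[!is.na(g)]
      if (length(g) < 2L) stop("need n >= 2 per group", call. = FALSE)
      list(m = mean(g), s = stats::sd(g), n = length(g))
    }
  }
  a <- as_stats(x); b <- as_stats(y)
  if (a$n < 2 || b$n < 2) stop("need n >= 2 per group", call. = FALSE)
  se2 <- a$s^2 / a$n + b$s^2 / b$n
  mean_diff <- a$m - b$m
  if (se2 == 0) {
    t <- if (mean_diff == 0) 0 else sign(mean_diff) * Inf
    df <- a$n + b$n - 2
  } else {
    t <- mean_diff / sqrt(se2)
    df <- se2^2 / ((a$s^2 / a$n)^2 / (a$n - 1) +
                     (b$s^2 / b$n)^2 / (b$n - 1))
  }
  p <- 2 * stats::pt(-abs(t), df)
  sp <- sqrt(((a$n - 1) * a$s^2 + (b$n - 1) * b$s^2) / (a$n + b$n - 2))
  d <- if (sp == 0) 0 else mean_diff / sp
  ci <- mean_diff + c(-1, 1) * stats::qt(0.975, df) * sqrt(se2)
  .ttest_result(t, df, p, d, mean_diff, ci, type = "welch")
}

#' Paired t test with the t/sqrt(n) effect-size convention
#'
#' @param x,y Equal-length paired numeric vectors; pairs with a missing
#'   value in either member are dropped.
#' @return An `ecitt_ttest`; `d` is the mean difference divided by the SD
#'   of the differences (equivalently \eqn{t/\sqrt{n}}).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    stop("paired vectors must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  d_i <- x[ok] - y[ok]
  n <- length(d_i)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  sd_d <- stats::sd(d_i)
  md <- mean(d_i)
  if (sd_d == 0) {
    t <- if (md == 0) 0 else sign(md) * Inf
    d <- 0
  } else {
    t <- md / (sd_d / sqrt(n))
    d <- md / sd_d
  }
  p <- 2 * stats::pt(-abs(t), n - 1)
  ci <- md + c(-1, 1) * stats::qt(0.975, n - 1) * sd_d / sqrt(n)
  .ttest_result(t, n - 1, p, d, md, ci, type = "paired")
}

#' Mixed / repeated-measures ANOVA with partial eta squared
#'
#' Univariate ANOVA for the balanced designs used in task validation: a
#' two-level within-subject condition factor crossed with an optional
#' between-subjects group factor (mixed design), or two within-subject
#' factors (fully within, e.g. 3 ages x 2 conditions). Participants with
#' any missing cell are dropped (listwise deletion); duplicate cells are
#' averaged. Partial eta squared is \eqn{SS_{effect} / (SS_{effect} +
#' SS_{error})} with the error term taken from the effect's own stratum.
#' No sphericity correction is applied.
#'
#' @param data Long-format data.frame.
#' @param dv Name of the numeric response column.
#' @param subject Name of the participant-id column.
#' @param within Character vector of within-subject factor column(s).
#' @param between Optional between-subjects factor column.
#' @return An object of class `ecitt_anova`: a data.frame with one row
#'   per effect (`effect`, `F`, `df1`, `df2`, `p`, `pes`) and attributes
#'   `n_subjects`, `dropped` (ids removed by listwise deletion).
#' @export
mixed_anova <- function(data, dv, subject, within, between = NULL) {
  stopifnot(all(c(dv, subject, within, between) %in% names(data)))
  facs <- c(within, between)
  d <- data[, c(dv, subject, facs)]
  names(d)[1:2] <- c(".y", ".id")
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d$.id <- factor(d$.id)
  for (f in facs) d[[f]] <- factor(d[[f]])
  # average duplicate cells
  d <- stats::aggregate(.y ~ ., data = d, FUN = mean)
  # listwise deletion: keep subjects with the full within-factor crossing
  n_cells <- prod(vapply(within, function(f) nlevels(d[[f]]), integer(1L)))
  counts <- table(d$.id)
  keep <- names(counts)[counts == n_cells]
  dropped <- setdiff(levels(d$.id), keep)
  d <- droplevels(d[d$.id %in% keep, , drop = FALSE])
  if (nlevels(d$.id) < 2L)
    stop("fewer than 2 complete participants", call. = FALSE)
  wterm <- paste(within, collapse = "*")
  if (is.null(between)) {
    fml <- stats::as.formula(paste0(
      ".y ~ ", wterm, " + Error(.id/(", wterm, "))"))
  } else {
    fml <- stats::as.formula(paste0(
      ".y ~ ", between, "*", wterm, " + Error(.id/(", wterm, "))"))
  }
  fit <- stats::aov(fml, data = d)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1L]]
    terms <- trimws(rownames(tab))
    res <- which(terms == "Residuals")
    if (!length(res)) next
    ss_err <- tab[res, "Sum Sq"]
    df_err <- tab[res, "Df"]
    for (j in setdiff(seq_along(terms), res)) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = terms[j],
        F = tab[j, "F value"],
        df1 = tab[j, "Df"],
        df2 = df_err,
        p = tab[j, "Pr(>F)"],
        pes = tab[j, "Sum Sq"] / (tab[j, "Sum Sq"] + ss_err),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_subjects") <- nlevels(d$.id)
  attr(out, "dropped") <- dropped
  class(out) <- c("ecitt_anova", "data.frame")
  out
}

#' @export
print.ecitt_anova <- function(x, ...) {
  if (length(attr(x, "dropped")))
    cat(sprintf("dropped %d incomplete participant(s): %s\n",
                length(attr(x, "dropped")),
                paste(attr(x, "dropped"), collapse = ", ")))
  for (j in seq_len(nrow(x)))
    cat(sprintf("%-20s F(%g, %g) = %.2f, p = %.4g, pes = %.2f\n",
                x$effect[j], x$df1[j], x$df2[j], x$F[j], x$p[j], x$pes[j]))
  invisible(x)
}

.cor_result <- function(r, n, p, ci, B = NA_integer_, partial = FALSE) {
  structure(list(r = r, n = n, p = p, ci_low = ci[1L], ci_high = ci[2L],
                 B = B, partial = partial), class = "ecitt_cor")
}

#' @export
print.ecitt_cor <- function(x, ...) {
  cat(sprintf("%sr = %.3f, n = %d, p = %.4g, 95%% CI [%.3f, %.3f]%s\n",
              if (x$partial) "partial " else "", x$r, x$n, x$p,
              x$ci_low, x$ci_high,
              if (is.na(x$B)) "" else sprintf(" (bootstrap, B = %d)",
                                              x$B)))
  invisible(x)
}

#' Pearson correlation with a seeded percentile bootstrap CI
#'
#' Pairwise-complete Pearson correlation; the confidence interval comes
#' from a percentile bootstrap resampling participants (pairs) with `B`
#' seeded resamples. Degenerate resamples (zero variance) are skipped.
#'
#' @param x,y Numeric vectors.
#' @param B Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `ecitt_cor`.
#' @export
correlate <- function(x, y, B = 1000L, seed = 1L, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; correlation undefined", call. = FALSE)
  r <- stats::cor(x, y)
  p <- stats::cor.test(x, y)$p.value
  ci <- .boot_ci_cor(cbind(x, y), B, seed, conf,
                     function(m) stats::cor(m[, 1L], m[, 2L]))
  .cor_result(r, n, p, ci, B = as.integer(B))
}

#' Partial Pearson correlation controlling for covariates
#'
#' Correlation between the least-squares residuals of `x` and `y` after
#' projecting each on the controls (with intercept). The p-value uses
#' `df = n - 2 - k` for `k` controls; the CI is a seeded percentile
#' bootstrap over complete rows.
#'
#' @param x,y Numeric vectors.
#' @param controls Numeric vector, matrix or data.frame of covariates.
#' @param B,seed,conf Bootstrap settings as in [correlate()].
#' @return An object of class `ecitt_cor` with `partial = TRUE`.
#' @export
partial_correlate <- function(x, y, controls, B = 1000L, seed = 1L,
                              conf = 0.95) {
  z <- as.matrix(controls)
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok, , drop = FALSE]
  n <- length(x); k <- ncol(z)
  if (n < 3L + k) stop("need n >= 3 + number of controls", call. = FALSE)
  pr <- function(m) {
    xm <- m[, 1L]; ym <- m[, 2L]; zm <- m[, -(1:2), drop = FALSE]
    rx <- stats::lm.fit(cbind(1, zm), xm)$residuals
    ry <- stats::lm.fit(cbind(1, zm), ym)$residuals
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
    stats::cor(rx, ry)
  }
  r <- pr(cbind(x, y, z))
  if (is.na(r)) stop("zero residual variance; partial correlation ",
                     "undefined", call. = FALSE)
  df <- n - 2L - k
  t <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df)
  ci <- .boot_ci_cor(cbind(x, y, z), B, seed, conf, pr)
  out <- .cor_result(r, n, p, ci, B = as.integer(B), partial = TRUE)
  out
}

.boot_ci_cor <- function(m, B, seed, conf, statistic) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n <- nrow(m)
  reps <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    mm <- m[idx, , drop = FALSE]
    if (any(apply(mm[, 1:2, drop = FALSE], 2L, stats::sd) == 0))
      return(NA_real_)
    statistic(mm)
  }, numeric(1L))
  reps <- reps[!is.na(reps)]
  if (!length(reps)) return(c(NA_real_, NA_real_))
  alpha <- (1 - conf) / 2
  unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7))
}

#' Linear vs quadratic age-trend comparison
#'
#' Hierarchical least squares for lifespan developmental trends: fits
#' `score ~ age`, then adds a quadratic term, and reports the increment F
#' test and change in R-squared. A u-shaped lifespan trend shows up as a
#' significant positive quadratic increment; a toddler-only age range
#' typically keeps the linear model.
#'
#' @param age Numeric ages (a single scale, e.g. months).
#' @param score Numeric scores (e.g. AccD).
#' @return An object of class `ecitt_age_trend`: list with `linear` and
#'   `quadratic` lm fits, `F`, `p`, `delta_r2`, and the two models'
#'   R-squared values.
#' @export
age_trend <- function(age, score) {
  ok <- stats::complete.cases(age, score)
  age <- age[ok]; score <- score[ok]
  if (length(age) <= 3L) stop("need n > 3", call. = FALSE)
  if (stats::sd(age) == 0) stop("degenerate ages", call. = FALSE)
  d <- data.frame(age = age, age2 = age^2, score = score)
  if (qr(cbind(1, d$age, d$age2))$rank < 3L)
    stop("collinear age terms; quadratic fit degenerate", call. = FALSE)
  m1 <- stats::lm(score ~ age, data = d)
  m2 <- stats::lm(score ~ age + age2, data = d)
  cmp <- stats::anova(m1, m2)
  r2 <- function(m) summary(m)$r.squared
  structure(list(linear = m1, quadratic = m2,
                 F = cmp$F[2L], p = cmp$`Pr(>F)`[2L],
                 delta_r2 = r2(m2) - r2(m1),
                 r2_linear = r2(m1), r2_quadratic = r2(m2)),
            class = "ecitt_age_trend")
}

#' @export
print.ecitt_age_trend <- function(x, ...) {
  cat(sprintf(
    "linear R2 = %.3f; quadratic R2 = %.3f; increment F = %.2f, p = %.4g\n",
    x$r2_linear, x$r2_quadratic, x$F, x$p))
  invisible(x)
}
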