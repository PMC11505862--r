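# Diagnostic-test evaluation statistics: confusion metrics with Wald
# intervals, diagnostic odds ratio, prevalence-adjusted ("unbiased")
# positive predictive value, McNemar / Cohen's g for paired classifiers,
# Friedman and one-sided Wilcoxon signed-rank tests with rank-biserial
# effect sizes for feature-set comparisons, high-confidence intervals for
# mean epoch probabilities, Beta posterior credible intervals, and
# AUC-based sample-size computation (Hanley-McNeil variance).

#' Confusion table
#'
#' @param TP,TN,FP,FN non-negative counts (cases are positives).
#' @return List of class `confusion_table`.
#' @export
confusion_table <- function(TP, TN, FP, FN) {
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("confusion counts must be non-negative integers")
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 N = TP + TN + FP + FN), class = "confusion_table")
}

#' Accuracy, sensitivity and specificity
#'
#' `Acc = (TP+TN)/N`, `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`. A metric whose
#' denominator is zero is returned as `NA` and named in the `undefined`
#' field rather than silently propagating NaN.
#'
#' @param ct a [confusion_table()].
#' @return List with `Acc`, `Se`, `Sp` (proportions) and `undefined`.
#' @export
confusion_metrics <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  undef <- character(0)
  acc <- if (ct$N > 0) (ct$TP + ct$TN) / ct$N else {undef <- c(undef, "Acc"); NA}
  se <- if (ct$TP + ct$FN > 0) ct$TP / (ct$TP + ct$FN) else {undef <- c(undef, "Se"); NA}
  sp <- if (ct$TN + ct$FP > 0) ct$TN / (ct$TN + ct$FP) else {undef <- c(undef, "Sp"); NA}
  list(Acc = acc, Se = se, Sp = sp, undefined = undef)
}

#' Wald (normal-approximation) binomial confidence interval, percent scale
#'
#' `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)`, clipped to \[0, 100\]. This
#' is the interval conventionally printed next to diagnostic metrics; an
#' exact Clopper-Pearson alternative is available via `method`.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n >= 1`.
#' @param level confidence level.
#' @param method `"wald"` (default) or `"clopper-pearson"`.
#' @return Numeric `c(lo, hi)` in percent.
#' @export
wald_ci <- function(k, n, level = 0.95, method = c("wald", "clopper-pearson")) {
  method <- match.arg(method)
  if (!is_count(k) || !is_count(n) || n < 1 || k > n)
    stopf("need 0 <= k <= n with n >= 1")
  if (method == "clopper-pearson") {
    lo <- if (k == 0) 0 else qbeta((1 - level) / 2, k, n - k + 1)
    hi <- if (k == n) 1 else qbeta(1 - (1 - level) / 2, k + 1, n - k)
    return(c(lo, hi) * 100)
  }
  p <- k / n
  z <- qnorm((1 + level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half)) * 100
}

#' Diagnostic odds ratio
#'
#' `DOR = (Se * Sp) / ((1 - Se) (1 - Sp))`; infinite (and flagged) when
#' either metric is perfect.
#'
#' @param se,sp sensitivity and specificity in \[0, 1\].
#' @return List with `dor` and `infinite` flag.
#' @export
dor <- function(se, sp) {
  if (se < 0 || se > 1 || sp < 0 || sp > 1) stopf("Se and Sp must be in [0,1]")
  if (se == 1 || sp == 1)
    return(list(dor = Inf, infinite = TRUE))
  list(dor = (se * sp) / ((1 - se) * (1 - sp)), infinite = FALSE)
}

#' Prevalence-adjusted (unbiased) positive predictive value
#'
#' The probability of disease given a positive test at the population
#' prevalence: `Se * prev / (Se * prev + (1 - prev)(1 - Sp))`.
#'
#' @param se,sp sensitivity and specificity in \[0, 1\].
#' @param prevalence disease prevalence in (0, 1).
#' @return Proportion in \[0, 1\] (`NA` with a flag if Se = 0 and Sp = 1).
#' @export
unbiased_ppv <- function(se, sp, prevalence) {
  if (prevalence <= 0 || prevalence >= 1)
    stopf("prevalence must be in (0, 1)")
  denom <- se * prevalence + (1 - prevalence) * (1 - sp)
  if (denom == 0) return(structure(NA_real_, undefined = TRUE))
  se * prevalence / denom
}

#' McNemar's test for two paired classifiers
#'
#' Compares per-subject correctness of two classifiers through the
#' discordant counts `b` (first correct, second wrong) and `c` (reverse).
#' The default is the exact two-sided binomial test (appropriate for small
#' cohorts); the continuity-corrected chi-square version is available.
#' Cohen's g is `|b / (b + c) - 0.5|`.
#'
#' @param correct_a,correct_b logical vectors of per-subject correctness,
#'   same subjects in the same order.
#' @param mode `"exact"` or `"chisq"`.
#' @return List with `p`, `b`, `c`, `cohens_g` (NA-flagged when b + c = 0).
#' @export
mcnemar_paired <- function(correct_a, correct_b, mode = c("exact", "chisq")) {
  mode <- match.arg(mode)
  if (length(correct_a) != length(correct_b))
    stopf("paired vectors must have equal length")
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  if (b + cc == 0)
    return(list(p = 1, b = b, c = cc, cohens_g = NA_real_,
                undefined_g = TRUE))
  p <- if (mode == "exact") {
    min(1, binom.test(b, b + cc, 0.5)$p.value)
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(p = p, b = b, c = cc, cohens_g = abs(b / (b + cc) - 0.5),
       undefined_g = FALSE)
}

#' Friedman rank test across feature sets
#'
#' Non-parametric repeated-measures comparison: rows are blocks (e.g. LOSO
#' datasets), columns are treatments (feature sets). Average ranks are used
#' for ties, with the standard tie correction; identical columns give
#' statistic 0 and p = 1.
#'
#' @param mat numeric matrix, blocks x treatments.
#' @return List with `statistic`, `df`, `p`, and `constant_rows` count.
#' @export
friedman_rank_test <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stopf("need at least 2 rows and 2 columns")
  ranks <- t(apply(mat, 1, rank))
  const <- sum(apply(mat, 1, function(r) length(unique(r)) == 1))
  rj <- colSums(ranks)
  stat_num <- 12 * sum((rj - n * (k + 1) / 2)^2)
  # tie correction: per block, sum of t^3 - t over tied group sizes
  tie_term <- sum(apply(mat, 1, function(r) {
    sizes <- as.vector(table(r))
    sum(sizes^3 - sizes)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  if (denom <= 0) return(list(statistic = 0, df = k - 1, p = 1,
                              constant_rows = const))
  statistic <- stat_num / denom
  list(statistic = statistic, df = k - 1,
       p = pchisq(statistic, df = k - 1, lower.tail = FALSE),
       constant_rows = const)
}

#' One-sided Wilcoxon signed-rank test with rank-biserial effect size
#'
#' Tests whether `a` tends to exceed `b` (paired, alternative "greater").
#' The exact signed-rank distribution is used for n <= 30 without ties or
#' zero differences; otherwise the normal approximation with tie
#' correction. The rank-biserial correlation is
#' `(W+ - W-) / (W+ + W-)`; any multiple-comparison (Bonferroni)
#' multiplier is the caller's responsibility.
#'
#' @param a,b paired numeric vectors, length >= 5.
#' @return List with `p`, `rank_biserial`, `w_pos`, `w_neg`, `n_effective`.
#' @export
wilcoxon_one_sided <- function(a, b) {
  if (length(a) != length(b)) stopf("paired vectors must have equal length")
  if (length(a) < 5) stopf("need at least 5 pairs")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(p = NA_real_, rank_biserial = NA_real_, w_pos = 0,
                w_neg = 0, n_effective = 0, undefined = TRUE))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  has_ties <- any(duplicated(abs(d)))
  if (n <= 30 && !has_ties) {
    # exact: P(W+ >= w_pos) under the null
    p <- psignrank(w_pos - 1, n, lower.tail = FALSE)
  } else {
    mu <- n * (n + 1) / 4
    tie_sizes <- as.vector(table(abs(d)))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_sizes^3 - tie_sizes) / 48
    p <- pnorm((w_pos - mu - 0.5) / sqrt(sig2), lower.tail = FALSE)
  }
  list(p = p, rank_biserial = (w_pos - w_neg) / (w_pos + w_neg),
       w_pos = w_pos, w_neg = w_neg, n_effective = n, undefined = FALSE)
}

#' High-confidence interval for a subject's mean epoch probability
#'
#' Normal-theory interval `mean +/- z * sd / sqrt(n)` at the requested
#' level (99.9% by default), clipped to \[0, 1\].
#'
#' @param probs epoch probabilities (>= 2).
#' @param level confidence level.
#' @return `c(lo, hi)`.
#' @export
mean_prob_ci <- function(probs, level = 0.999) {
  if (length(probs) < 2) stopf("need at least 2 probabilities")
  z <- qnorm((1 + level) / 2)
  m <- mean(probs)
  half <- z * sd(probs) / sqrt(length(probs))
  c(max(0, m - half), min(1, m + half))
}

#' Beta posterior credible interval for thresholded epoch predictions
#'
#' Treats the count of epochs predicted as case (probability >= 0.5) among
#' n epochs as Bernoulli draws with a Beta prior (uniform by default); the
#' equal-tailed posterior interval of the case rate is returned.
#'
#' @param k epochs predicted case.
#' @param n total epochs.
#' @param prior `c(alpha, beta)` of the Beta prior.
#' @param level credible level.
#' @return `c(lo, hi)`.
#' @export
beta_credible_interval <- function(k, n, prior = c(1, 1), level = 0.999) {
  if (!is_count(k) || !is_count(n) || k > n) stopf("need 0 <= k <= n")
  a <- prior[1] + k
  b <- prior[2] + n - k
  alpha <- 1 - level
  c(qbeta(alpha / 2, a, b), qbeta(1 - alpha / 2, a, b))
}

hanley_mcneil_se <- function(auc, n) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n - 1) * (q1 - auc^2) + (n - 1) * (q2 - auc^2)) /
         n^2)
}

#' Sample size for detecting an AUC difference
#'
#' Smallest equal group size n such that the AUC difference is at least
#' `z_alpha * SE(auc0, n) + z_beta * SE(auc1, n)` with Hanley-McNeil
#' standard errors - a one-sided z-test of the AUC against a null value.
#'
#' @param auc0 null AUC, `0.5 <= auc0 < auc1`.
#' @param auc1 alternative AUC, `< 1`.
#' @param alpha one-sided type I error rate.
#' @param power target power.
#' @param n_max search cap.
#' @return n per group.
#' @export
auc_sample_size <- function(auc0 = 0.7, auc1 = 0.95, alpha = 0.05,
                            power = 0.95, n_max = 1e6) {
  if (!(auc0 >= 0.5 && auc0 < auc1 && auc1 < 1))
    stopf("need 0.5 <= auc0 < auc1 < 1")
  za <- qnorm(1 - alpha)
  zb <- qnorm(power)
  delta <- auc1 - auc0
  for (n in 2:n_max) {
    if (delta >= za * hanley_mcneil_se(auc0, n) +
        zb * hanley_mcneil_se(auc1, n))
      return(n)
  }
  stopf("power not reachable within n <= %g", n_max)
}
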