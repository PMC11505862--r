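# Diagnostic evaluation statistics: frozen closed-form values, published
# benchmark numbers, and brute-force oracles.

test_that("confusion metrics reproduce the benchmark rows", {
  m <- confusion_metrics(confusion_table(TP = 14, TN = 14, FP = 0, FN = 0))
  expect_equal(c(m$Acc, m$Se, m$Sp), c(1, 1, 1))
  m <- confusion_metrics(confusion_table(TP = 13, TN = 14, FP = 0, FN = 1))
  expect_equal(round(m$Se * 100, 2), 92.86)
  expect_equal(round(m$Acc * 100, 2), 96.43)
  m <- confusion_metrics(confusion_table(5, 5, 5, 5))
  expect_equal(c(m$Acc, m$Se, m$Sp), c(0.5, 0.5, 0.5))
  und <- confusion_metrics(confusion_table(TP = 0, TN = 3, FP = 2, FN = 0))
  expect_true("Se" %in% und$undefined)
  expect_true(is.na(und$Se))
})

test_that("Wald intervals match the published bounds and behave", {
  expect_equal(round(wald_ci(13, 14), 2), c(79.37, 100))
  expect_equal(round(wald_ci(6, 14), 2), c(16.93, 68.78))
  expect_equal(wald_ci(14, 14)[2], 100)  # clipped at k = n
  for (k in c(3, 9, 14)) {
    ci <- wald_ci(k, 20)
    expect_true(ci[1] <= 100 * k / 20 && 100 * k / 20 <= ci[2])
  }
  expect_lt(diff(wald_ci(5000, 10000)), diff(wald_ci(5, 10)))
  cp <- wald_ci(13, 14, method = "clopper-pearson")
  expect_true(cp[1] > 0 && cp[2] <= 100)
  expect_error(wald_ci(5, 4), "k <= n")
})

test_that("diagnostic odds ratio matches the published values", {
  expect_equal(round(dor(0.7857, 0.8571)$dor, 2), 21.99)
  expect_equal(round(dor(0.3571, 0.2857)$dor, 2), 0.22)
  expect_equal(dor(0.5, 0.5)$dor, 1)
  inf <- dor(1, 0.8)
  expect_true(is.infinite(inf$dor) && inf$infinite)
  # symmetry and the DOR > 1 boundary
  for (i in 1:20) {
    se <- runif(1, 0.05, 0.95); sp <- runif(1, 0.05, 0.95)
    expect_equal(dor(se, sp)$dor, dor(sp, se)$dor)
    expect_equal(dor(se, sp)$dor > 1, se + sp > 1)
  }
})

test_that("unbiased PPV matches the published values and is monotone", {
  expect_equal(round(unbiased_ppv(0.7857, 0.8571, 0.03) * 100, 2), 14.53)
  expect_equal(round(unbiased_ppv(0.3571, 0.2857, 0.03) * 100, 2), 1.52)
  expect_equal(round(unbiased_ppv(0.7857, 0.8571, 0.01) * 100, 2), 5.26)
  expect_equal(round(unbiased_ppv(0.3571, 0.2857, 0.01) * 100, 2), 0.50)
  expect_equal(unbiased_ppv(0.6, 1, 0.03), 1)  # no false positives
  prevs <- seq(0.01, 0.3, length.out = 10)
  ppvs <- vapply(prevs, function(p) unbiased_ppv(0.8, 0.9, p), 1)
  expect_true(all(diff(ppvs) > 0))
  sps <- seq(0.5, 0.99, length.out = 10)
  ppvs <- vapply(sps, function(s) unbiased_ppv(0.8, s, 0.03), 1)
  expect_true(all(diff(ppvs) > 0))
})

test_that("McNemar handles discordant-pair cases exactly", {
  # b = c: symmetric null
  r <- mcnemar_paired(c(TRUE, FALSE, TRUE, FALSE), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(r$p, 1)
  # b = 4, c = 0: two-sided exact p = 2 * 0.5^4
  r <- mcnemar_paired(rep(TRUE, 4), rep(FALSE, 4))
  expect_equal(r$p, 0.125)
  expect_equal(r$cohens_g, 0.5)
  # g = |3/4 - 1/2|
  r <- mcnemar_paired(c(T, T, T, F, T), c(F, F, F, T, T))
  expect_equal(r$b, 3); expect_equal(r$c, 1)
  expect_equal(r$cohens_g, 0.25)
  # no discordance
  r <- mcnemar_paired(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(r$p, 1)
  expect_true(r$undefined_g)
})

test_that("Friedman statistic agrees with the rank-based oracle", {
  # identical columns: no information, statistic 0, p 1
  m <- matrix(rep(1:6, 3), ncol = 3)
  r <- friedman_rank_test(m)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # hand-ranked chi-square oracle (no ties): chi2 = 12/(nk(k+1)) sum Rj^2 - 3n(k+1)
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(rnorm(18), ncol = 3)
    r <- friedman_rank_test(m)
    rj <- colSums(t(apply(m, 1, rank)))
    n <- nrow(m); k <- ncol(m)
    oracle <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
    expect_equal(r$statistic, oracle, tolerance = 1e-12)
    # independent reference route
    ref <- stats::friedman.test(m)
    expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("one-sided Wilcoxon matches full sign enumeration for small n", {
  enum_p <- function(d) {
    # exact null: all 2^n sign assignments of the rank magnitudes
    r <- rank(abs(d))
    n <- length(d)
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- signs %*% r
    mean(w_all >= w_obs)
  }
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n), 3)
    while (any(d == 0) || any(duplicated(abs(d)))) d <- round(rnorm(n), 3)
    r <- wilcoxon_one_sided(d, rep(0, n))
    expect_equal(r$p, enum_p(d), tolerance = 1e-12)
  }
  # n = 6, all positive: p = 1/64
  r <- wilcoxon_one_sided(2:7, rep(0, 6))
  expect_equal(r$p, 1 / 64)
  expect_equal(r$rank_biserial, 1)
  # antisymmetric differences: zero rank-biserial
  r <- wilcoxon_one_sided(c(1, -1, 2, -2, 3, -3), rep(0, 6))
  expect_equal(r$rank_biserial, 0)
})

test_that("mean-probability interval follows the closed form", {
  expect_equal(mean_prob_ci(rep(0.7, 5)), c(0.7, 0.7))
  set.seed(3)
  p <- rnorm(4800, 0.8, 0.1)
  ci <- mean_prob_ci(p)
  expect_equal(diff(ci) / 2, qnorm(0.9995) * sd(p) / sqrt(4800),
               tolerance = 1e-10)
  expect_lt(abs(diff(ci) / 2 - 3.2905 * 0.1 / sqrt(4800)), 5e-4)
  ci <- mean_prob_ci(c(0.99, 0.999, 1))
  expect_true(ci[1] >= 0 && ci[2] <= 1)
  expect_error(mean_prob_ci(0.5), "at least 2")
})

test_that("Beta credible interval matches closed-form quantiles", {
  # k = n = 10, uniform prior: posterior Beta(11, 1), whose CDF is x^11, so
  # the equal-tailed bounds are q^(1/11)
  ci <- beta_credible_interval(10, 10)
  expect_equal(ci[1], 0.0005^(1 / 11), tolerance = 1e-12)
  expect_equal(ci[2], 0.9995^(1 / 11), tolerance = 1e-12)
  expect_gt(ci[2], 0.99995)
  # mirror symmetry
  ci0 <- beta_credible_interval(0, 10)
  expect_equal(ci0, 1 - rev(ci), tolerance = 1e-12)
  # posterior concentration
  w1 <- diff(beta_credible_interval(5, 10))
  w2 <- diff(beta_credible_interval(50, 100))
  expect_lt(w2, w1)
})

test_that("AUC sample size reproduces the design value", {
  expect_equal(auc_sample_size(0.7, 0.95, 0.05, 0.95), 13)
  expect_lte(auc_sample_size(0.7, 0.95, 0.05, 0.80), 13)
  expect_gt(auc_sample_size(0.7, 0.72, 0.05, 0.95), 100)
  expect_error(auc_sample_size(0.7, 0.705, 0.05, 0.95, n_max = 50),
               "not reachable")
  expect_error(auc_sample_size(0.9, 0.8), "auc0 < auc1")
})
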