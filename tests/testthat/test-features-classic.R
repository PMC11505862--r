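# Classic time- and frequency-domain EMG features: frozen hand-computed
# values plus algebraic property checks on random epochs.

test_that("scalar features match hand-computed values", {
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_equal(rms(rep(-2.5, 10)), 2.5)
  expect_equal(v_order(c(1, 2, 2, 4), 2), sqrt(6.25))
  expect_equal(v_order(c(1, 2, 3), 1), 2)  # arithmetic mean for v = 1
  expect_equal(log_detector(c(1, 10, 100)), 10)              # geometric mean
  expect_equal(log_detector(c(1, 10, 100), "base10"), exp(1)) # literal form
  expect_equal(log_detector(rep(4.2, 7)), 4.2)
  expect_equal(mav(c(1, -2, 3)), 2)
  tm <- temporal_moments(c(2))
  expect_equal(c(tm$TM3, tm$TM4, tm$TM5), c(8, 16, 32))
  tm <- temporal_moments(c(1, -1))
  expect_equal(c(tm$TM3, tm$TM4, tm$TM5), c(0, 1, 0))
  wm <- waveform_measures(c(0, 1, 0))
  expect_equal(c(wm$WL, wm$DASDV, wm$SI), c(2, 1, 1))
  wm <- waveform_measures(rep(3, 5))
  expect_equal(c(wm$WL, wm$DASDV, wm$SI), c(0, 0, 45))
  expect_error(rms(numeric(0)), "empty")
  expect_error(v_order(1:3, 0), "positive")
})

test_that("threshold counts agree with index-pair enumeration", {
  tc <- threshold_counts(c(0.5, -0.5, 0.5, -0.5), 0.01)
  expect_equal(tc, list(MYOP = 1, ZC = 3L, SSC = 2L, WAMP = 3L))
  tc <- threshold_counts(rep(0.5, 6), 0.01)
  expect_equal(c(tc$ZC, tc$SSC, tc$WAMP), c(0L, 0L, 0L))
  expect_equal(tc$MYOP, 1)
  tc <- threshold_counts(rep(0.001, 6), 0.01)
  expect_equal(tc$MYOP, 0)
  # threshold 0 on an alternating-sign signal: every adjacent pair crosses
  x <- rep(c(1, -1), 10)
  expect_equal(threshold_counts(x, 0)$ZC, length(x) - 1L)
  # brute-force oracle over all index pairs/triples
  enum_counts <- function(x, thr) {
    n <- length(x)
    zc <- 0L; wamp <- 0L; ssc <- 0L
    for (i in 1:(n - 1)) {
      if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= thr) zc <- zc + 1L
      if (abs(x[i] - x[i + 1]) >= thr) wamp <- wamp + 1L
    }
    for (i in 2:(n - 1))
      if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) >= thr) ssc <- ssc + 1L
    list(ZC = zc, SSC = ssc, WAMP = wamp,
         MYOP = mean(abs(x) >= thr))
  }
  set.seed(5)
  for (i in 1:25) {
    x <- rnorm(40, sd = 0.3)
    thr <- runif(1, 0, 0.3)
    got <- threshold_counts(x, thr)
    want <- enum_counts(x, thr)
    expect_identical(got[c("ZC", "SSC", "WAMP")],
                     want[c("ZC", "SSC", "WAMP")])
    expect_equal(got$MYOP, want$MYOP)
  }
})

test_that("spectral features locate sinusoidal power", {
  fs <- 2048; n <- 1024
  t <- (0:(n - 1)) / fs
  sf <- spectral_features(sin(2 * pi * 100 * t), fs)
  expect_lt(abs(sf$MNF - 100), 2)
  expect_lt(abs(sf$MDF - 100), 2)
  sf2 <- spectral_features(sin(2 * pi * 100 * t) + sin(2 * pi * 300 * t), fs)
  expect_lt(abs(sf2$MNF - 200), 2)
  # scale invariance
  x <- rnorm(n)
  expect_equal(spectral_features(x, fs), spectral_features(7 * x, fs))
  expect_error(spectral_features(rep(0, n), fs), "all-zero")
})

test_that("algebraic invariants hold on random epochs", {
  set.seed(9)
  for (i in 1:40) {
    x <- rnorm(256, sd = runif(1, 0.01, 2))
    n <- length(x)
    expect_equal(waveform_measures(x)$SI, n * rms(x)^2, tolerance = 1e-9)
    expect_equal(v_order(x, 2), rms(x), tolerance = 1e-12)
    expect_lte(mav(x), rms(x))
    expect_lte(rms(x), max(abs(x)))
    tc <- threshold_counts(x, 0.05)
    expect_true(tc$MYOP >= 0 && tc$MYOP <= 1)
    expect_true(is.integer(tc$ZC) && is.integer(tc$SSC) &&
                  is.integer(tc$WAMP))
    # raising the threshold never increases the gated counts
    lo <- threshold_counts(x, 0.02); hi <- threshold_counts(x, 0.2)
    expect_lte(hi$ZC, lo$ZC); expect_lte(hi$SSC, lo$SSC)
    expect_lte(hi$WAMP, lo$WAMP); expect_lte(hi$MYOP, lo$MYOP)
    # scaling homogeneity of the temporal moments
    tm1 <- temporal_moments(x); tm3 <- temporal_moments(3 * x)
    expect_equal(tm3$TM3, 27 * tm1$TM3)
    expect_equal(tm3$TM4, 81 * tm1$TM4)
    expect_equal(tm3$TM5, 243 * tm1$TM5)
  }
})

test_that("the vectorised feature table agrees with the scalar routes", {
  set.seed(21)
  x <- matrix(rnorm(5 * 1024, sd = 0.2), nrow = 5)
  eps <- toy_epoch_set(x)
  tab <- classic_features(eps)
  expect_equal(nrow(tab), 5)
  expect_setequal(attr(tab, "feature_names"),
                  c("RMS", "V", "LOG", "MAV", "MYOP", "ZC", "SSC", "WAMP",
                    "TM3", "TM4", "TM5", "WL", "DASDV", "SI", "MNF", "MDF"))
  for (i in 1:5) {
    xi <- x[i, ]
    expect_equal(tab$RMS[i], rms(xi))
    expect_equal(tab$LOG[i], log_detector(xi))
    expect_equal(tab$MAV[i], mav(xi))
    tc <- threshold_counts(xi, 0.01)
    expect_equal(tab$MYOP[i], tc$MYOP)
    expect_equal(tab$ZC[i], as.numeric(tc$ZC))
    expect_equal(tab$SSC[i], as.numeric(tc$SSC))
    expect_equal(tab$WAMP[i], as.numeric(tc$WAMP))
    wm <- waveform_measures(xi)
    expect_equal(tab$WL[i], wm$WL)
    expect_equal(tab$DASDV[i], wm$DASDV)
    expect_equal(tab$SI[i], wm$SI)
    sf <- spectral_features(xi, fs_std)
    expect_equal(tab$MNF[i], sf$MNF)
    expect_equal(tab$MDF[i], sf$MDF)
  }
})
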