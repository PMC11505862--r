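# Morlet transform and phase-amplitude coherence: analytic fidelity on
# sinusoids, null behaviour on noise, and recovery of injected coupling.

test_that("Morlet wavelets have unit energy and measure sinusoids faithfully", {
  fs <- fs_std
  for (f in c(5, 50, 150, 340)) {
    k <- pacemg:::morlet_kernel(f, fs, morlet_params())
    expect_equal(sum(Mod(k)^2), 1, tolerance = 1e-6)
  }
  t <- (0:(4 * fs - 1)) / fs
  x <- sin(2 * pi * 50 * t)
  W <- morlet_transform(x, fs, 50)
  interior <- (fs):(3 * fs)
  amp <- Mod(W[1, interior])
  expect_lt((max(amp) - min(amp)) / mean(amp), 0.02)
  # unwrapped phase advances at 2*pi*f within 1%
  ph <- Arg(W[1, interior])
  slope <- mean(atan2(sin(diff(ph)), cos(diff(ph)))) * fs / (2 * pi)
  expect_lt(abs(slope - 50) / 50, 0.01)
  # linearity
  W2 <- morlet_transform(2 * x, fs, 50)
  expect_equal(W2, 2 * W, tolerance = 1e-12)
})

test_that("unsupported low frequencies are dropped with a warning", {
  x <- rnorm(2048)  # 1 s: a 2 Hz wavelet (support ~4.5 s) cannot fit
  expect_warning(W <- morlet_transform(x, fs_std, c(2, 100)), "support")
  expect_equal(attr(W, "freqs"), 100)
  expect_error(suppressWarnings(morlet_transform(rnorm(256), fs_std, 2)),
               "no frequency")
})

test_that("coherence detects deterministic coupling and is scale-invariant", {
  x <- coupled_signal(4)
  coh <- pac_coherence(x, fs_std, 10, 150)
  expect_gte(coh, 0.8)
  expect_equal(pac_coherence(5 * x, fs_std, 10, 150), coh, tolerance = 1e-12)
  expect_error(pac_coherence(x[1:2048], fs_std, 10, 150, nperseg = 2048),
               "Welch segments")
  expect_error(suppressWarnings(pac_coherence(x[1:300], fs_std, 10, 150)),
               "too short")
  expect_error(pac_coherence(x, fs_std, 150, 10), "exceed")
})

test_that("white noise yields null-level coherence", {
  set.seed(31)
  vals <- replicate(100, {
    pac_coherence(rnorm(4 * fs_std), fs_std, 10, 150)
  })
  expect_lt(median(vals), 0.3)
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("comodulogram recovers injected coupling and masks correctly", {
  cfg <- sim_config(n_cases = 1, n_controls = 1, duration_s = 8,
                    muscles = "ECR", channels_per_muscle = 1,
                    coupled_muscles = "ECR", bad_channel_rate = 0, seed = 5)
  rec <- simulate_subject(cfg, 1, "case")
  com <- comodulogram(rec$samples[1, ], fs_std, seq(4, 30, 2),
                      seq(30, 350, 10))
  expect_true(all(com >= 0 & com <= 1, na.rm = TRUE))
  idx <- which(unclass(com) == max(com, na.rm = TRUE), arr.ind = TRUE)
  fp_hat <- as.numeric(rownames(com)[idx[1]])
  fa_hat <- as.numeric(colnames(com)[idx[2]])
  truth <- attr(rec, "truth")
  expect_lte(abs(fp_hat - truth$f_p), 2 + abs(truth$f_p - 10))
  expect_lte(abs(fa_hat - truth$f_a), 10 + abs(truth$f_a - 150))
  # zero-coupling channel stays below the null of the grid maximum
  ctrl <- simulate_subject(sim_config(n_cases = 1, n_controls = 1,
                                      duration_s = 8, muscles = "ECR",
                                      channels_per_muscle = 1,
                                      coupled_muscles = "ECR",
                                      coupling_strength = 0,
                                      bad_channel_rate = 0, seed = 6),
                           1, "case")
  grid_p <- c(8, 10, 12); grid_a <- c(130, 150, 170)
  m0_max <- max(comodulogram(ctrl$samples[1, ], fs_std, grid_p, grid_a),
                na.rm = TRUE)
  set.seed(77)
  null_max <- replicate(40, {
    max(comodulogram(rnorm(8 * fs_std), fs_std, grid_p, grid_a),
        na.rm = TRUE)
  })
  expect_lt(m0_max, quantile(null_max, 0.95))
})

test_that("comodulogram vectorisation is a named, invertible flattening", {
  # bookkeeping contract on a synthetic grid (no masked cells)
  fp <- seq(2, 28, 2); fa <- seq(30, 350, 10)
  vals <- matrix(runif(length(fp) * length(fa)), length(fp),
                 dimnames = list(fp, fa))
  com <- structure(vals, class = c("comodulogram", "matrix"),
                   phase_freqs = fp, amp_freqs = fa)
  v <- vectorize_comodulogram(com)
  expect_length(v, 14 * 33)
  expect_equal(names(v)[1:2], c("PAC_2_30", "PAC_2_40"))
  back <- comodulogram_from_vector(v, fp, fa)
  expect_equal(unclass(back), unclass(com))
  # masked cells are excluded and the count matches the mask
  com2 <- comodulogram(coupled_signal(2), fs_std, c(20, 40), c(30, 150))
  v2 <- vectorize_comodulogram(com2)
  expect_length(v2, sum(outer(c(20, 40), c(30, 150), function(p, a) a > p)))
  expect_false("PAC_40_30" %in% names(v2))
})

test_that("the PAC feature table shares windows and stays deterministic", {
  cfg <- sim_config(n_cases = 1, n_controls = 1, duration_s = 6,
                    muscles = "ECR", channels_per_muscle = 2,
                    coupled_muscles = "ECR", bad_channel_rate = 0, seed = 9)
  rec <- emg_bandpass(simulate_subject(cfg, 1, "case"))
  eps <- segment_epochs(rec)
  tab <- pac_features(eps, phase_freqs = c(8, 10, 12),
                      amp_freqs = c(130, 150, 170))
  expect_equal(nrow(tab), nrow(eps$info))
  expect_length(attr(tab, "feature_names"), 9)
  # 12 epochs -> one 8-epoch block plus a merged trailing block; epochs in
  # the same block carry identical comodulogram vectors
  expect_equal(tab$PAC_10_150[1], tab$PAC_10_150[8])
  tab2 <- pac_features(eps, phase_freqs = c(8, 10, 12),
                       amp_freqs = c(130, 150, 170))
  expect_identical(tab, tab2)
})
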