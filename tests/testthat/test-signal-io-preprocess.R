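# Band-pass conditioning, bad-channel handling, 500 ms epoching, and file
# round-trips.

make_rec <- function(x, fs = fs_std, muscles = "ECR", per = NULL,
                     mask = NULL, group = "control") {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (is.null(per)) per <- nrow(x) / length(muscles)
  labels <- data.frame(muscle = rep(muscles, each = per),
                       index = rep(seq_len(per), length(muscles)))
  emg_recording(x, fs, labels, "t01", group, mask)
}

test_that("the band-pass passes the band and rejects the stop band", {
  fs <- fs_std
  t <- (0:(4 * fs - 1)) / fs
  rec <- make_rec(sin(2 * pi * 100 * t))
  out <- emg_bandpass(rec)
  mid <- fs:(3 * fs)
  gain <- sqrt(mean(out$samples[1, mid]^2)) / sqrt(mean(rec$samples[1, mid]^2))
  expect_gt(gain, 0.95); expect_lt(gain, 1.05)
  rec5 <- make_rec(sin(2 * pi * 5 * t))
  out5 <- emg_bandpass(rec5)
  expect_lt(sqrt(mean(out5$samples^2)) / sqrt(mean(rec5$samples^2)), 0.10)
  zero <- emg_bandpass(make_rec(rep(0, 1000)))
  expect_true(all(zero$samples == 0))
  expect_error(emg_bandpass(make_rec(rnorm(100), fs = 512)), "Nyquist")
  # causal single-pass mode differs but keeps the pass band alive
  causal <- emg_bandpass(rec, filter_spec(zero_phase = FALSE))
  expect_false(identical(causal$samples, out$samples))
  expect_gt(sqrt(mean(causal$samples[1, mid]^2)), 0.6)
})

test_that("bad channels are dropped with the stated edge behaviour", {
  x <- matrix(rnorm(28 * 100), nrow = 28)
  rec <- make_rec(x, muscles = c("ECR", "EDC", "ECU", "FCR"), per = 7)
  expect_identical(drop_bad_channels(rec), rec)  # all-false mask
  rec$bad_channel_mask[c(3, 17)] <- TRUE
  kept <- drop_bad_channels(rec)
  expect_equal(nrow(kept$samples), 26)
  expect_equal(nrow(kept$channel_labels), 26)
  rec$bad_channel_mask <- rep(TRUE, 28)
  expect_error(drop_bad_channels(rec), "rejected")
  rec$bad_channel_mask <- c(rep(TRUE, 7), rep(FALSE, 21))
  expect_warning(kept <- drop_bad_channels(rec), "ECR")
  expect_equal(sort(unique(kept$channel_labels$muscle)),
               c("ECU", "EDC", "FCR"))
})

test_that("epoch counts follow floor(T fs / 1024) per channel", {
  fs <- fs_std
  # 9.1 s: 18636 samples -> 18 complete 1024-sample epochs
  rec <- make_rec(rnorm(round(9.1 * fs)))
  eps <- segment_epochs(rec)
  expect_equal(nrow(eps$x), 18)
  expect_equal(ncol(eps$x), 1024)
  # exactly one epoch
  expect_equal(nrow(segment_epochs(make_rec(rnorm(1024)))$x), 1)
  # 26 channels x 18 windows
  x26 <- matrix(rnorm(26 * round(9.1 * fs)), nrow = 26)
  eps26 <- segment_epochs(make_rec(x26, muscles = "ECR", per = 26))
  expect_equal(nrow(eps26$x), 468)
  expect_error(segment_epochs(make_rec(rnorm(500))), "too short")
  # epochs tile the signal in order
  expect_equal(eps$x[1, ], rec$samples[1, 1:1024])
  expect_equal(eps$x[2, ], rec$samples[1, 1025:2048])
  # overlap mode
  eps_ov <- segment_epochs(make_rec(rnorm(2048)), overlap = 0.5)
  expect_equal(nrow(eps_ov$x), 3)
})

test_that("filtering and segmenting commute", {
  rec <- make_rec(matrix(rnorm(2 * 4096), nrow = 2), muscles = "ECR",
                  per = 2)
  a <- segment_epochs(emg_bandpass(rec))
  filt <- emg_bandpass(rec)
  b_x <- rbind(
    t(sapply(1:4, function(w) filt$samples[1, ((w - 1) * 1024 + 1):(w * 1024)])),
    t(sapply(1:4, function(w) filt$samples[2, ((w - 1) * 1024 + 1):(w * 1024)])))
  expect_equal(a$x, b_x)
})

test_that("CSV round-trip is bit-exact and EDF is 12-bit faithful", {
  set.seed(19)
  rec <- make_rec(matrix(rnorm(3 * 2500, sd = 0.2), nrow = 3),
                  muscles = c("ECR", "EDC", "ECU"), per = 1, group = "case")
  rec$bad_channel_mask[2] <- TRUE
  csv <- tempfile(fileext = ".csv")
  write_recording_csv(rec, csv)
  back <- read_recording_csv(csv)
  expect_identical(back$samples, rec$samples)
  expect_identical(back$bad_channel_mask, rec$bad_channel_mask)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_identical(back$group, rec$group)
  edf <- tempfile(fileext = ".edf")
  write_recording_edf(rec, edf)
  back_edf <- read_recording_edf(edf)
  expect_equal(back_edf$fs, rec$fs)
  expect_equal(back_edf$channel_labels$muscle, rec$channel_labels$muscle)
  expect_equal(back_edf$group, "case")
  n <- ncol(rec$samples)
  err <- max(abs(back_edf$samples[, 1:n] - rec$samples))
  expect_lt(err, max(abs(rec$samples)) / 2047 * 1.01)
  unlink(c(csv, paste0(csv, ".json"), edf))
})

test_that("feature tables round-trip through CSV", {
  tab <- toy_feature_table(2, 5)
  path <- tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back$f1, tab$f1)
  expect_equal(back$subject_id, tab$subject_id)
  expect_equal(attr(back, "feature_names"), c("f1", "f2"))
  unlink(path)
})
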