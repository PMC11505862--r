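#' Configuration for the synthetic HD-sEMG cohort generator
#'
#' Describes a two-group cohort of multi-channel surface-EMG recordings with
#' the statistical structure the analysis pipeline assumes: band-limited
#' (20-450 Hz) stochastic EMG at 2048 Hz, seven single-differential channels
#' for each of four forearm muscles, per-subject exercise durations in the
#' 9.1-95.9 s range, and - for the case group - phase-amplitude coupling
#' injected into selected muscles: a low-frequency pacing rhythm at
#' `pac_phase_freq` whose phase modulates the amplitude of a carrier at
#' `pac_amp_freq`. After injection every channel is rescaled to `rms_target`
#' so whole-recording RMS is matched across groups and classic amplitude
#' features carry little class signal.
#'
#' @param n_cases,n_controls subjects per group.
#' @param fs sampling rate (Hz).
#' @param duration_s seconds of signal per subject; `NULL` (default) draws
#'   each subject's duration uniformly from `duration_range`.
#' @param duration_range range used when `duration_s` is `NULL`.
#' @param muscles muscle labels.
#' @param channels_per_muscle single-differential channels per muscle.
#' @param band (low, high) Hz limits of the stochastic EMG spectrum.
#' @param pac_phase_freq,pac_amp_freq nominal coupling pair (Hz).
#' @param coupling_strength dimensionless coupling strength m in \[0, 1\].
#' @param rhythm_gain amplitude of the low-frequency pacing rhythm relative
#'   to `m * rms_target`; the rhythm must be present in the signal for its
#'   phase to be observable at all.
#' @param coupled_muscles muscles receiving the coupled component in cases.
#' @param subject_jitter relative s.d. of per-subject jitter on the phase
#'   frequency, amplitude frequency and coupling strength.
#' @param rms_target per-channel RMS amplitude (mV scale; the default 0.2
#'   keeps the classic 0.01 amplitude threshold inside the sensitive range
#'   of all four gated counting features).
#' @param bad_channel_rate probability that a channel is flagged bad
#'   (default approximates the typical handful of rejected electrodes).
#' @param carrier `"sinusoid"` for an analyzable pure-tone carrier with
#'   exact ground truth (default) or `"noise"` for a more realistic
#'   band-limited noise carrier centred on `pac_amp_freq`.
#' @param control_carrier `"matched"` (default) gives control subjects an
#'   unmodulated carrier of equal average power plus the same pacing
#'   rhythm, so classic amplitude and spectral features are matched across
#'   groups and only the phase-amplitude dependence separates them;
#'   `"none"` leaves controls as pure band-limited noise (the groups then
#'   also differ in band-power distribution, which amplitude-blind
#'   features can exploit).
#' @param seed integer; identical seeds give bit-identical cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 14, n_controls = 14, fs = 2048,
                       duration_s = NULL, duration_range = c(9.1, 95.9),
                       muscles = c("ECR", "EDC", "ECU", "FCR"),
                       channels_per_muscle = 7, band = c(20, 450),
                       pac_phase_freq = 10, pac_amp_freq = 150,
                       coupling_strength = 0.8, rhythm_gain = 0.5,
                       coupled_muscles = c("ECR", "EDC"),
                       subject_jitter = 0.02, rms_target = 0.2,
                       bad_channel_rate = 0.12,
                       carrier = c("sinusoid", "noise"),
                       control_carrier = c("matched", "none"), seed = 1L) {
  carrier <- match.arg(carrier)
  control_carrier <- match.arg(control_carrier)
  if (!is_count(n_cases) || !is_count(n_controls))
    stopf("n_cases and n_controls must be non-negative integers")
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stopf("band must lie inside (0, fs/2)")
  if (pac_amp_freq <= pac_phase_freq)
    stopf("pac_amp_freq must exceed pac_phase_freq")
  if (coupling_strength < 0 || coupling_strength > 1)
    stopf("coupling_strength must be in [0, 1]")
  if (!all(coupled_muscles %in% muscles))
    stopf("coupled_muscles must be a subset of muscles")
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    fs = fs, duration_s = duration_s, duration_range = duration_range,
    muscles = muscles, channels_per_muscle = as.integer(channels_per_muscle),
    band = band, pac_phase_freq = pac_phase_freq,
    pac_amp_freq = pac_amp_freq, coupling_strength = coupling_strength,
    rhythm_gain = rhythm_gain, coupled_muscles = coupled_muscles,
    subject_jitter = subject_jitter, rms_target = rms_target,
    bad_channel_rate = bad_channel_rate, carrier = carrier,
    control_carrier = control_carrier, seed = as.integer(seed)
  ), class = "sim_config")
}

rms_of <- function(x) sqrt(mean(x^2))

#' Simulate one subject's HD-sEMG recording
#'
#' Every channel is band-limited Gaussian noise scaled to the target RMS.
#' For case subjects, channels of the coupled muscles additionally receive
#' the coupling component: a low-frequency pacing rhythm plus a
#' higher-frequency carrier whose amplitude is modulated by that rhythm's
#' phase, with per-subject jittered parameters and per-channel random
#' phases. With the default matched control carrier, control subjects
#' receive the same pacing rhythm plus an unmodulated carrier of equal
#' average power, so both groups share amplitude and band-power structure
#' and only the phase-amplitude dependence differs. After injection every
#' channel is band-limited and rescaled to the target RMS, so
#' whole-recording amplitude is matched across groups exactly. Both groups
#' consume the identical random-number stream, so at
#' `coupling_strength = 0` cases and controls are bit-identical for the
#' same subject seed.
#'
#' @param cfg a [sim_config()].
#' @param subject_index integer used to derive the subject seed.
#' @param group `"case"` or `"control"`.
#' @return An [emg_recording()]; `attr(, "truth")` holds the subject's true
#'   coupling parameters and duration.
#' @export
simulate_subject <- function(cfg, subject_index, group = c("control", "case")) {
  stopifnot(inherits(cfg, "sim_config"))
  group <- match.arg(group)
  sseed <- derive_seed(cfg$seed, subject_index)
  with_seed(sseed, {
    dur <- if (is.null(cfg$duration_s))
      runif(1, cfg$duration_range[1], cfg$duration_range[2])
    else cfg$duration_s
    nlen <- as.integer(round(dur * cfg$fs))
    if (nlen < round(0.5 * cfg$fs))
      stopf("subject %d: duration %.3f s too short for one 500 ms epoch",
            subject_index, dur)
    jit <- function(x) x * (1 + cfg$subject_jitter * rnorm(1))
    f_p <- jit(cfg$pac_phase_freq)
    f_a <- jit(cfg$pac_amp_freq)
    m <- min(1, max(0, jit(cfg$coupling_strength)))
    nch <- length(cfg$muscles) * cfg$channels_per_muscle
    labels <- data.frame(
      muscle = rep(cfg$muscles, each = cfg$channels_per_muscle),
      index = rep(seq_len(cfg$channels_per_muscle), length(cfg$muscles)))
    ba <- butter_bandpass(2, cfg$band[1], cfg$band[2], cfg$fs)
    tvec <- (seq_len(nlen) - 1) / cfg$fs
    samples <- matrix(0, nrow = nch, ncol = nlen)
    for (ch in seq_len(nch)) {
      noise <- apply_filter(rnorm(nlen), ba$b, ba$a, zero_phase = TRUE)
      noise <- noise / rms_of(noise) * cfg$rms_target
      phi <- runif(1, 0, 2 * pi)
      psi <- runif(1, 0, 2 * pi)
      coupled <- labels$muscle[ch] %in% cfg$coupled_muscles
      carrier_wave <- if (cfg$carrier == "sinusoid") {
        cos(2 * pi * f_a * tvec + psi)
      } else {
        cw <- apply_filter(rnorm(nlen), ba$b, ba$a, TRUE)
        # narrow the noise carrier around f_a with a Gaussian spectral window
        cw_f <- fft(cw)
        fr <- (seq_len(nlen) - 1) / nlen * cfg$fs
        fr <- pmin(fr, cfg$fs - fr)
        w <- exp(-((fr - f_a)^2) / (2 * (f_a / 7)^2))
        cw <- Re(fft(cw_f * w, inverse = TRUE)) / nlen
        cw / max(rms_of(cw), .Machine$double.eps) / sqrt(2)
      }
      modulator <- if (group == "case" || cfg$control_carrier == "none") {
        # amplitude locked to the pacing rhythm's phase
        0.5 * (1 + cos(2 * pi * f_p * tvec + phi))
      } else {
        # matched-power constant amplitude: E[(0.5(1+cos))^2] = 3/8
        sqrt(3 / 8)
      }
      a_t <- m * cfg$rms_target *
        (cfg$rhythm_gain * cos(2 * pi * f_p * tvec + phi) +
           modulator * carrier_wave)
      inject <- if (group == "case") 1 else
        if (cfg$control_carrier == "matched") 1 else 0
      x <- noise + inject * coupled * a_t
      # confine the composite to the stated band (the pacing rhythm enters
      # attenuated, like any sub-band content surviving the front end),
      # then rescale so whole-recording RMS is group-matched exactly
      x <- apply_filter(x, ba$b, ba$a, zero_phase = TRUE)
      samples[ch, ] <- x / rms_of(x) * cfg$rms_target
    }
    mask <- runif(nch) < cfg$bad_channel_rate
    if (all(mask)) mask[sample.int(nch, 1)] <- FALSE
    rec <- emg_recording(samples, cfg$fs, labels,
                         subject_id = sprintf("%s%02d",
                                              if (group == "case") "p" else "s",
                                              subject_index),
                         group = group, bad_channel_mask = mask)
    attr(rec, "truth") <- list(duration_s = dur, f_p = f_p, f_a = f_a,
                               m = if (group == "case") m else 0,
                               seed = sseed)
    rec
  })
}

#' Simulate a two-group cohort
#'
#' Generates `n_cases + n_controls` recordings with per-subject seeds
#' derived deterministically from the cohort seed, plus a manifest mapping
#' subject id to group, duration and true coupling parameters.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `emg_cohort` with elements `recordings` (list of
#'   [emg_recording()]) and `manifest` (data.frame).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_cases < 1 || cfg$n_controls < 1)
    stopf("need at least one subject per group")
  groups <- c(rep("case", cfg$n_cases), rep("control", cfg$n_controls))
  index <- c(seq_len(cfg$n_cases), seq_len(cfg$n_controls))
  offset <- c(rep(0L, cfg$n_cases), rep(cfg$n_cases, cfg$n_controls))
  recs <- vector("list", length(groups))
  rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    recs[[i]] <- simulate_subject(cfg, index[i] + offset[i], groups[i])
    recs[[i]]$subject_id <- sprintf("%s%02d",
                                    if (groups[i] == "case") "p" else "s",
                                    index[i])
    tr <- attr(recs[[i]], "truth")
    rows[[i]] <- data.frame(
      subject_id = recs[[i]]$subject_id, group = groups[i],
      duration_s = tr$duration_s, f_p = tr$f_p, f_a = tr$f_a, m = tr$m,
      seed = tr$seed, n_bad_channels = sum(recs[[i]]$bad_channel_mask),
      stringsAsFactors = FALSE)
  }
  structure(list(recordings = recs, manifest = do.call(rbind, rows)),
            class = "emg_cohort")
}
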