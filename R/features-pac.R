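# Phase-amplitude coupling. A complex Morlet transform supplies, per
# frequency, the amplitude envelope (magnitude) and instantaneous phase
# (argument); coupling between a phase frequency f_p and an amplitude
# frequency f_a is the magnitude-squared Welch coherence between
# cos(phase at f_p) and the envelope at f_a, read off at the Welch bin
# nearest f_p. Evaluating the coherence over a grid of (f_p, f_a) pairs
# yields the comodulogram.

#' Morlet transform parameters
#'
#' The width parameter is interpreted as the number of cycles: the Gaussian
#' envelope has temporal s.d. `cycles / (2 * pi * f)`, giving a spectral
#' s.d. of `f / cycles`. An absolute-seconds mode is available for
#' completeness (`sigma_mode = "seconds"`, in which case `cycles` is the
#' envelope s.d. in seconds at every frequency). Wavelets are normalised to
#' unit L2 energy and truncated at four envelope s.d.
#'
#' @param cycles wavelet width (default 7 cycles).
#' @param sigma_mode `"cycles"` (default) or `"seconds"`.
#' @return List of class `morlet_params`.
#' @export
morlet_params <- function(cycles = 7, sigma_mode = c("cycles", "seconds")) {
  sigma_mode <- match.arg(sigma_mode)
  if (!is_scalar_num(cycles) || cycles <= 0) stopf("cycles must be positive")
  structure(list(cycles = cycles, sigma_mode = sigma_mode),
            class = "morlet_params")
}

morlet_kernel <- function(f, fs, params) {
  sig_t <- if (params$sigma_mode == "cycles") params$cycles / (2 * pi * f)
           else params$cycles
  half <- round(4 * sig_t * fs)
  t <- (-half:half) / fs
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sig_t^2))
  w / sqrt(sum(Mod(w)^2))
}

#' Complex Morlet time-frequency transform
#'
#' Convolves the signal with a unit-energy complex Morlet wavelet at each
#' requested frequency ("same"-length centred output). The magnitude of a
#' row is the amplitude envelope at that frequency; its argument is the
#' instantaneous phase. Frequencies whose truncated wavelet support exceeds
#' the signal length are dropped with a warning.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param freqs frequencies (Hz), each inside (0, fs/2).
#' @param params a [morlet_params()].
#' @return Complex matrix, one row per retained frequency (rownames are the
#'   frequencies); `attr(, "freqs")` gives the retained frequencies.
#' @export
morlet_transform <- function(x, fs, freqs, params = morlet_params()) {
  stopifnot(inherits(params, "morlet_params"))
  if (any(freqs <= 0 | freqs >= fs / 2))
    stopf("frequencies must lie inside (0, fs/2)")
  n <- length(x)
  kernels <- lapply(freqs, morlet_kernel, fs = fs, params = params)
  keep <- vapply(kernels, length, 1L) <= n
  if (!all(keep))
    warnf("dropping %d frequenc%s whose wavelet support exceeds the signal",
          sum(!keep), if (sum(!keep) == 1) "y" else "ies")
  if (!any(keep)) stopf("no frequency has support within the signal")
  freqs <- freqs[keep]; kernels <- kernels[keep]
  maxlen <- max(vapply(kernels, length, 1L))
  nfft <- nextn(n + maxlen - 1, 2)
  X <- fft(c(x, rep(0, nfft - n)))
  out <- matrix(0i, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    k <- kernels[[i]]
    K <- fft(c(k, rep(0i, nfft - length(k))))
    y <- fft(X * K, inverse = TRUE) / nfft
    lag <- (length(k) - 1) / 2
    out[i, ] <- y[(lag + 1):(lag + n)]
  }
  rownames(out) <- freqs
  attr(out, "freqs") <- freqs
  out
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))

# Windowed, demeaned segment FFTs for Welch estimation: returns a complex
# matrix (frequency bins x segments).
welch_segments <- function(x, nperseg, overlap = 0.5) {
  n <- length(x)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- hann_window(nperseg)
  seg <- matrix(0, nperseg, length(starts))
  for (j in seq_along(starts)) {
    s <- x[starts[j]:(starts[j] + nperseg - 1L)]
    seg[, j] <- (s - mean(s)) * w
  }
  mvfft(seg)
}

#' Phase-amplitude coherence for one frequency pair
#'
#' Extracts the phase carrier `cos(arg W(f_phase, t))` and the amplitude
#' envelope `|W(f_amp, t)|` from the Morlet transform, then estimates their
#' magnitude-squared coherence with Welch averaging (Hann segments,
#' 50% overlap) and reads it off at the Welch frequency bin nearest
#' `f_phase`. At least two Welch segments are required, otherwise the
#' coherence estimate is identically one.
#'
#' @param x numeric vector (one analysis window; at least ~4 s recommended
#'   so the phase frequency is resolvable).
#' @param fs sampling rate (Hz).
#' @param f_phase,f_amp frequency pair in Hz, `f_amp > f_phase`.
#' @param params a [morlet_params()].
#' @param nperseg Welch segment length in samples.
#' @param overlap Welch segment overlap fraction.
#' @return Coherence in \[0, 1\].
#' @export
pac_coherence <- function(x, fs, f_phase, f_amp, params = morlet_params(),
                          nperseg = 256, overlap = 0.5) {
  if (f_amp <= f_phase) stopf("f_amp must exceed f_phase")
  W <- morlet_transform(x, fs, c(f_phase, f_amp), params)
  if (nrow(W) < 2)
    stopf("signal too short to support both analysis frequencies")
  ph <- cos(Arg(W[1, ]))
  amp <- Mod(W[2, ])
  coherence_pair(ph, amp, fs, f_phase, nperseg, overlap)
}

coherence_pair <- function(ph, amp, fs, f_eval, nperseg, overlap) {
  n <- length(ph)
  nseg <- floor((n - nperseg * overlap) / (nperseg * (1 - overlap)))
  if (nseg < 2)
    stopf("need at least 2 Welch segments (have %d samples, nperseg %d)",
          n, nperseg)
  Fp <- welch_segments(ph, nperseg, overlap)
  Fa <- welch_segments(amp, nperseg, overlap)
  bin <- which.min(abs((seq_len(floor(nperseg / 2)) ) * fs / nperseg - f_eval))
  b <- bin + 1L  # skip DC row
  pxy <- mean(Fp[b, ] * Conj(Fa[b, ]))
  pxx <- mean(Mod(Fp[b, ])^2)
  pyy <- mean(Mod(Fa[b, ])^2)
  if (pxx == 0 || pyy == 0) return(0)
  min(1, Mod(pxy)^2 / (pxx * pyy))
}

#' Phase-amplitude comodulogram
#'
#' Evaluates [pac_coherence()] on every (phase, amplitude) grid cell with
#' `f_amp > f_phase`; masked cells are `NA`. The default grid covers phase
#' 2-30 Hz in 2 Hz steps and amplitude 30-350 Hz in 10 Hz steps; "paper
#' mode" (`phase_freqs = amp_freqs = 1:350`) is accepted but large.
#' Morlet transforms are shared across cells.
#'
#' @param x numeric analysis window.
#' @param fs sampling rate (Hz).
#' @param phase_freqs,amp_freqs grid frequencies in Hz.
#' @param params a [morlet_params()].
#' @param nperseg,overlap Welch settings, see [pac_coherence()].
#' @return Matrix of class `comodulogram` (phase frequencies in rows,
#'   amplitude frequencies in columns, values in \[0, 1\]), with attributes
#'   `phase_freqs` and `amp_freqs`.
#' @export
comodulogram <- function(x, fs, phase_freqs = seq(2, 30, by = 2),
                         amp_freqs = seq(30, 350, by = 10),
                         params = morlet_params(), nperseg = 256,
                         overlap = 0.5) {
  if (!length(phase_freqs) || !length(amp_freqs)) stopf("empty grid")
  n <- length(x)
  if (n < 2 * nperseg) {  # too short for >= 2 standard Welch segments
    nperseg <- max(64L, 2^floor(log2(n / 3)))
  }
  Wp <- morlet_transform(x, fs, phase_freqs, params)
  phase_freqs <- attr(Wp, "freqs")
  Wa <- morlet_transform(x, fs, amp_freqs, params)
  amp_freqs <- attr(Wa, "freqs")
  # precompute Welch segment FFTs per frequency series
  Fp <- lapply(seq_along(phase_freqs), function(i)
    welch_segments(cos(Arg(Wp[i, ])), nperseg, overlap))
  Fa <- lapply(seq_along(amp_freqs), function(j)
    welch_segments(Mod(Wa[j, ]), nperseg, overlap))
  half <- floor(nperseg / 2)
  fbins <- (1:half) * fs / nperseg
  vals <- matrix(NA_real_, length(phase_freqs), length(amp_freqs),
                 dimnames = list(phase_freqs, amp_freqs))
  for (i in seq_along(phase_freqs)) {
    b <- which.min(abs(fbins - phase_freqs[i])) + 1L
    pxx <- mean(Mod(Fp[[i]][b, ])^2)
    for (j in seq_along(amp_freqs)) {
      if (amp_freqs[j] <= phase_freqs[i]) next
      pxy <- mean(Fp[[i]][b, ] * Conj(Fa[[j]][b, ]))
      pyy <- mean(Mod(Fa[[j]][b, ])^2)
      vals[i, j] <- if (pxx == 0 || pyy == 0) 0
                    else min(1, Mod(pxy)^2 / (pxx * pyy))
    }
  }
  structure(vals, class = c("comodulogram", "matrix"),
            phase_freqs = phase_freqs, amp_freqs = amp_freqs)
}

#' Flatten a comodulogram to a named feature vector
#'
#' Row-major flattening (amplitude frequency varies fastest) with stable
#' names `PAC_<fp>_<fa>`; masked cells (`f_amp <= f_phase`) are excluded.
#' [comodulogram_from_vector()] is the exact inverse.
#'
#' @param com a `comodulogram`.
#' @return Named numeric vector.
#' @export
vectorize_comodulogram <- function(com) {
  stopifnot(inherits(com, "comodulogram"))
  fp <- attr(com, "phase_freqs"); fa <- attr(com, "amp_freqs")
  flat <- as.vector(t(unclass(com)))
  names(flat) <- paste0("PAC_", rep(fp, each = length(fa)), "_",
                        rep(fa, times = length(fp)))
  flat[!is.na(flat)]
}

#' Rebuild a comodulogram from its flattened form
#'
#' @param v named vector from [vectorize_comodulogram()].
#' @param phase_freqs,amp_freqs the grid used originally.
#' @return A `comodulogram` (masked cells `NA`).
#' @export
comodulogram_from_vector <- function(v, phase_freqs, amp_freqs) {
  vals <- matrix(NA_real_, length(phase_freqs), length(amp_freqs),
                 dimnames = list(phase_freqs, amp_freqs))
  for (nm in names(v)) {
    parts <- strsplit(sub("^PAC_", "", nm), "_")[[1]]
    vals[parts[1], parts[2]] <- v[[nm]]
  }
  structure(vals, class = c("comodulogram", "matrix"),
            phase_freqs = phase_freqs, amp_freqs = amp_freqs)
}

#' PAC feature table for an epoch set
#'
#' A 500 ms epoch cannot resolve low phase frequencies on its own, so PAC
#' is estimated on longer per-channel analysis windows: consecutive epochs
#' of each (subject, muscle, channel) series are concatenated into blocks
#' of `window_epochs` epochs (4 s by default) and the block's flattened
#' comodulogram is assigned to every epoch inside it. Channels shorter than
#' one block fall back to a single window with shortened Welch segments.
#'
#' @param epochs an `epoch_set`.
#' @param phase_freqs,amp_freqs comodulogram grid (Hz).
#' @param window_epochs epochs per analysis window.
#' @param params a [morlet_params()].
#' @param nperseg Welch segment length for full-size windows.
#' @return data.frame feature table with `PAC_<fp>_<fa>` columns.
#' @export
pac_features <- function(epochs, phase_freqs = seq(2, 30, by = 2),
                         amp_freqs = seq(30, 350, by = 10),
                         window_epochs = 8, params = morlet_params(),
                         nperseg = 256) {
  stopifnot(inherits(epochs, "epoch_set"))
  info <- epochs$info
  # fix the retained grid up-front from the standard window length so every
  # block (including longer merged trailing blocks) shares one feature set
  std_len <- window_epochs * ncol(epochs$x)
  support_ok <- function(f) {
    length(morlet_kernel(f, epochs$fs, params)) <= std_len
  }
  keep_p <- vapply(phase_freqs, support_ok, TRUE)
  if (!all(keep_p))
    warnf("dropping %d phase frequenc%s whose wavelet support exceeds the %g s analysis window",
          sum(!keep_p), if (sum(!keep_p) == 1) "y" else "ies",
          std_len / epochs$fs)
  phase_freqs <- phase_freqs[keep_p]
  amp_freqs <- amp_freqs[vapply(amp_freqs, support_ok, TRUE)]
  key <- paste(info$subject_id, info$muscle, info$channel_index, sep = "\r")
  rows_by_channel <- split(seq_len(nrow(info)), key)
  grid_names <- paste0("PAC_", rep(phase_freqs, each = length(amp_freqs)),
                       "_", rep(amp_freqs, times = length(phase_freqs)))
  grid_mask <- rep(amp_freqs, times = length(phase_freqs)) >
    rep(phase_freqs, each = length(amp_freqs))
  grid_names <- grid_names[grid_mask]
  feat <- matrix(NA_real_, nrow(info), length(grid_names),
                 dimnames = list(NULL, grid_names))
  for (rows in rows_by_channel) {
    rows <- rows[order(info$segment_index[rows])]
    nblock <- max(1L, length(rows) %/% window_epochs)
    block_of <- pmin(ceiling(seq_along(rows) / window_epochs), nblock)
    for (b in seq_len(nblock)) {
      sel <- rows[block_of == b]
      xw <- as.vector(t(epochs$x[sel, , drop = FALSE]))
      com <- suppressWarnings(
        comodulogram(xw, epochs$fs, phase_freqs, amp_freqs, params,
                     nperseg = nperseg))
      v <- vectorize_comodulogram(com)
      feat[sel, names(v)] <- matrix(v, nrow = length(sel), ncol = length(v),
                                    byrow = TRUE)
    }
  }
  out <- cbind(info, as.data.frame(feat))
  attr(out, "feature_names") <- colnames(feat)
  out
}
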