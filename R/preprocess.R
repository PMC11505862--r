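#' Band-pass filter specification
#'
#' EMG recordings are conditioned with a second-order Butterworth band-pass
#' (20-450 Hz by default, the usual surface-EMG band). With
#' `zero_phase = TRUE` the filter is run forward and backward, doubling the
#' effective order and cancelling group delay; this is appropriate for
#' offline analysis where causality does not matter.
#'
#' @param band numeric length-2, (low, high) edge frequencies in Hz.
#' @param order filter order of the underlying design (per edge); the
#'   band-pass transfer function has `2 * order` poles.
#' @param zero_phase logical; forward-backward filtering (default) or a
#'   single causal pass.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(band = c(20, 450), order = 2, zero_phase = TRUE) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1])
    stopf("band must be (low, high) with 0 < low < high")
  if (!is_count(order) || order < 1) stopf("order must be a positive integer")
  structure(list(band = as.numeric(band), order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)), class = "filter_spec")
}

# Digital Butterworth band-pass design via the analog prototype, the
# lowpass-to-bandpass transform and the bilinear transform (matched to the
# classical formulation; checked against reference designs during
# development). Returns list(b, a).
butter_bandpass <- function(order, low, high, fs) {
  if (high >= fs / 2) stopf("band edge %g Hz is at or above Nyquist (%g Hz)",
                            high, fs / 2)
  n <- order
  # analog prototype poles (Butterworth circle)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # prewarped edges
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # lowpass -> bandpass: each pole splits in two; n zeros at s = 0
  p_lp <- p * bw / 2
  p_bp <- c(p_lp + sqrt(p_lp^2 - w0^2), p_lp - sqrt(p_lp^2 - w0^2))
  z_bp <- rep(0 + 0i, n)
  k_bp <- bw^n
  # bilinear transform
  z_d <- (1 + z_bp / fs2) / (1 - z_bp / fs2)
  p_d <- (1 + p_bp / fs2) / (1 - p_bp / fs2)
  k_d <- k_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  z_d <- c(z_d, rep(-1 + 0i, length(p_bp) - length(z_bp)))
  poly_from_roots <- function(r) {
    coefs <- 1 + 0i
    for (ri in r) coefs <- c(coefs, 0) - c(0, coefs * ri)
    coefs
  }
  b <- Re(poly_from_roots(z_d)) * k_d
  a <- Re(poly_from_roots(p_d))
  list(b = b, a = a)
}

# Initial filter state producing step-response steady state (classical
# filtfilt start-up handling), solved from the companion form.
lfilter_zi <- function(b, a) {
  n <- length(a)
  if (n == 1) return(numeric(0))
  comp <- rbind(-a[-1], cbind(diag(1, n - 2), 0))
  iminus <- diag(n - 1) - t(comp)
  bvec <- b[-1] - a[-1] * b[1]
  solve(iminus, bvec)
}

filt_once <- function(b, a, x, zi_scale) {
  .lfilter_cpp(b, a, x, zi_scale)
}

# Zero-phase filtering with odd-reflection padding and matched initial
# conditions; single causal pass available.
apply_filter <- function(x, b, a, zero_phase = TRUE) {
  if (!zero_phase) {
    return(filt_once(b, a, x, numeric(length(a) - 1)))
  }
  ntaps <- max(length(a), length(b))
  padlen <- min(length(x) - 1, 3 * ntaps)
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[seq(padlen + 1, 2)],
           x,
           2 * x[length(x)] - x[seq(length(x) - 1, length(x) - padlen)])
  y <- filt_once(b, a, ext, zi * ext[1])
  y <- rev(filt_once(b, a, rev(y), zi * y[length(y)]))
  y[seq(padlen + 1, padlen + length(x))]
}

#' Band-pass filter a recording
#'
#' Applies the Butterworth band-pass of `spec` to every channel. With
#' zero-phase filtering the signal is passed forward and backward through
#' the filter (zero group delay, squared magnitude response).
#'
#' @param rec an [emg_recording()].
#' @param spec a [filter_spec()].
#' @return The filtered recording; `attr(, "filter_spec")` records the spec.
#' @export
emg_bandpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "emg_recording"), inherits(spec, "filter_spec"))
  ba <- butter_bandpass(spec$order, spec$band[1], spec$band[2], rec$fs)
  out <- rec
  for (i in seq_len(nrow(rec$samples)))
    out$samples[i, ] <- apply_filter(rec$samples[i, ], ba$b, ba$a,
                                     spec$zero_phase)
  attr(out, "filter_spec") <- spec
  out
}

#' Remove channels flagged as bad
#'
#' Drops the channels marked in the recording's bad-channel mask, mirroring
#' the manual rejection of poor-quality electrodes. If every channel of a
#' muscle is removed a warning is raised and the subject is retained with
#' its remaining muscles; if all channels are flagged the subject is
#' rejected.
#'
#' @param rec an [emg_recording()].
#' @return The recording restricted to the retained channels.
#' @export
drop_bad_channels <- function(rec) {
  stopifnot(inherits(rec, "emg_recording"))
  mask <- rec$bad_channel_mask
  if (all(mask))
    stopf("subject %s: all %d channels flagged bad; subject rejected",
          rec$subject_id, length(mask))
  if (!any(mask)) return(rec)
  lost <- setdiff(unique(rec$channel_labels$muscle),
                  unique(rec$channel_labels$muscle[!mask]))
  if (length(lost))
    warnf("subject %s: all channels of muscle(s) %s removed",
          rec$subject_id, paste(lost, collapse = ", "))
  out <- rec
  out$samples <- rec$samples[!mask, , drop = FALSE]
  out$channel_labels <- rec$channel_labels[!mask, , drop = FALSE]
  rownames(out$channel_labels) <- NULL
  out$bad_channel_mask <- rep(FALSE, sum(!mask))
  out
}

#' Cut a recording into fixed-length epochs
#'
#' Segments every retained channel into consecutive non-overlapping windows
#' of `epoch_s` seconds (500 ms by default, i.e. 1024 samples at 2048 Hz).
#' The trailing remainder shorter than one epoch is discarded. Each
#' (channel, window) pair becomes one analysis row.
#'
#' @param rec an [emg_recording()] (bad channels should be dropped first).
#' @param epoch_s epoch length in seconds.
#' @param overlap fraction of overlap between consecutive epochs; 0
#'   (non-overlapping) by default.
#' @return An object of class `epoch_set`: a list with `x` (epochs in rows,
#'   samples in columns), `info` (one metadata row per epoch: subject_id,
#'   group, muscle, channel_index, segment_index) and `fs`.
#' @export
segment_epochs <- function(rec, epoch_s = 0.5, overlap = 0) {
  stopifnot(inherits(rec, "emg_recording"))
  nlen <- round(epoch_s * rec$fs)
  nt <- ncol(rec$samples)
  if (nt < nlen)
    stopf("subject %s: recording too short (%d samples) for one %g s epoch",
          rec$subject_id, nt, epoch_s)
  step <- max(1L, as.integer(round(nlen * (1 - overlap))))
  starts <- seq(1L, nt - nlen + 1L, by = step)
  nch <- nrow(rec$samples)
  x <- matrix(0, nrow = nch * length(starts), ncol = nlen)
  info <- data.frame(
    subject_id = rec$subject_id,
    group = rec$group,
    muscle = rep(rec$channel_labels$muscle, each = length(starts)),
    channel_index = rep(rec$channel_labels$index, each = length(starts)),
    segment_index = rep(seq_along(starts), times = nch),
    stringsAsFactors = FALSE
  )
  row <- 1L
  for (ch in seq_len(nch)) {
    for (s in starts) {
      x[row, ] <- rec$samples[ch, s:(s + nlen - 1L)]
      row <- row + 1L
    }
  }
  structure(list(x = x, info = info, fs = rec$fs), class = "epoch_set")
}

#' Combine epoch sets from several recordings
#'
#' @param ... `epoch_set` objects (or a single list of them).
#' @return One `epoch_set` with rows stacked in order.
#' @export
bind_epochs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "epoch_set"))
    sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, TRUE, "epoch_set")))
  fs <- unique(vapply(sets, function(s) s$fs, 1))
  if (length(fs) != 1) stopf("epoch sets have differing sampling rates")
  structure(list(
    x = do.call(rbind, lapply(sets, `[[`, "x")),
    info = do.call(rbind, lapply(sets, `[[`, "info")),
    fs = fs
  ), class = "epoch_set")
}
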