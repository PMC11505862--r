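#' Construct a multi-channel sEMG recording
#'
#' The basic container used throughout the package: a channels-by-time
#' amplitude matrix with sampling rate, per-channel muscle labels and
#' subject-level metadata.
#'
#' @param samples numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param channel_labels data.frame with columns `muscle` (character) and
#'   `index` (integer within muscle), one row per channel.
#' @param subject_id subject identifier string.
#' @param group `"case"` or `"control"`.
#' @param bad_channel_mask logical vector, `TRUE` for channels flagged as
#'   poor quality; defaults to all `FALSE`.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs, channel_labels, subject_id,
                          group = c("control", "case"),
                          bad_channel_mask = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  group <- match.arg(group)
  if (!is_scalar_num(fs) || fs <= 0) stopf("fs must be a positive number")
  nch <- nrow(samples)
  if (nrow(channel_labels) != nch)
    stopf("channel_labels has %d rows but there are %d channels",
          nrow(channel_labels), nch)
  if (is.null(bad_channel_mask)) bad_channel_mask <- rep(FALSE, nch)
  if (length(bad_channel_mask) != nch)
    stopf("bad_channel_mask length %d does not match %d channels",
          length(bad_channel_mask), nch)
  structure(list(
    samples = samples,
    fs = fs,
    channel_labels = data.frame(muscle = as.character(channel_labels$muscle),
                                index = as.integer(channel_labels$index),
                                stringsAsFactors = FALSE),
    subject_id = as.character(subject_id),
    group = group,
    bad_channel_mask = as.logical(bad_channel_mask)
  ), class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> %s (%s): %d channels x %d samples @ %g Hz (%.1f s), %d flagged bad\n",
    x$subject_id, x$group, nrow(x$samples), ncol(x$samples), x$fs,
    ncol(x$samples) / x$fs, sum(x$bad_channel_mask)))
  invisible(x)
}

channel_names <- function(rec) {
  paste0(rec$channel_labels$muscle, "_", rec$channel_labels$index)
}
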