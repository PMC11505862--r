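# Readers and writers. CSV is the bit-exact interchange format (samples are
# printed with 17 significant digits, enough to round-trip doubles); EDF
# (continuous, 16-bit) is provided for interoperability with standard
# biosignal tooling and round-trips to its 12-bit-scale quantization.

#' Write a recording as CSV
#'
#' One column per channel (header `MUSCLE_i`), one row per sample. A JSON
#' sidecar (`<path>.json`) carries the sampling rate, labels, group and
#' bad-channel mask so the reader can rebuild the full recording.
#'
#' @param rec an [emg_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  header <- paste(channel_names(rec), collapse = ",")
  body <- apply(rec$samples, 2, function(col)
    paste(sprintf("%.17g", col), collapse = ","))
  writeLines(c(header, body), path)
  sidecar <- list(fs = rec$fs, subject_id = rec$subject_id, group = rec$group,
                  muscle = rec$channel_labels$muscle,
                  index = rec$channel_labels$index,
                  bad_channel_mask = rec$bad_channel_mask)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording_csv()]
#'
#' @param path CSV file (its `.json` sidecar must sit next to it).
#' @return An [emg_recording()].
#' @export
read_recording_csv <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) stopf("missing sidecar %s", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  lines <- readLines(path)
  vals <- strsplit(lines[-1], ",", fixed = TRUE)
  samples <- vapply(vals, as.numeric, numeric(length(meta$muscle)))
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  emg_recording(samples, meta$fs,
                data.frame(muscle = meta$muscle, index = meta$index),
                meta$subject_id, meta$group, meta$bad_channel_mask)
}

#' Write a recording as EDF (continuous, 16-bit)
#'
#' Minimal EDF writer: one data record per second, all channels at the
#' recording's sampling rate, physical range set symmetrically from the
#' data, digital range -2048..2047 (12-bit scale). A trailing partial
#' second is zero-padded in the file; the true length is recoverable from
#' the recording duration in the header only to whole records, so prefer
#' CSV when exact lengths matter.
#'
#' @param rec an [emg_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  ns <- nrow(rec$samples)
  spr <- as.integer(rec$fs)  # samples per record (1 s records)
  n_rec <- as.integer(ceiling(ncol(rec$samples) / spr))
  pad <- function(s, width) formatC(substr(s, 1, width), width = width,
                                    flag = "-")
  phys_max <- apply(abs(rec$samples), 1, max)
  phys_max[phys_max == 0] <- 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8),
    pad(paste0("subj ", rec$subject_id, " grp ", rec$group), 80),
    pad("synthetic sEMG", 80),
    pad("01.01.24", 8), pad("00.00.00", 8),
    pad(as.character(256 * (ns + 1)), 8),
    pad("", 44),
    pad(as.character(n_rec), 8),
    pad("1", 8),
    pad(as.character(ns), 4)), con, eos = NULL)
  labs <- channel_names(rec)
  field <- function(values, width)
    writeChar(paste(vapply(values, pad, "", width), collapse = ""), con,
              eos = NULL)
  field(labs, 16)
  field(rep("sEMG", ns), 80)
  field(rep("mV", ns), 8)
  field(sprintf("%.6g", -phys_max), 8)
  field(sprintf("%.6g", phys_max), 8)
  field(rep("-2048", ns), 8)
  field(rep("2047", ns), 8)
  field(rep("HP:20Hz LP:450Hz", ns), 80)
  field(rep(as.character(spr), ns), 8)
  field(rep("", ns), 32)
  gain <- (2 * phys_max) / 4095  # EDF affine map, digital -2048..2047
  total <- n_rec * spr
  x <- rec$samples
  if (total > ncol(x))
    x <- cbind(x, matrix(0, ns, total - ncol(x)))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((x[ch, idx] + phys_max[ch]) / gain[ch])) - 2048L
      dig <- pmin(2047L, pmax(-2048L, dig))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_recording_edf()]
#'
#' Supports continuous EDF with equal sampling rate across channels.
#' Subject id and group are parsed from the patient field when present.
#'
#' @param path EDF file.
#' @return An [emg_recording()].
#' @export
read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  patient <- trimws(substr(hdr, 9, 88))
  n_rec <- as.integer(trimws(substr(hdr, 237, 244)))
  dur <- as.numeric(trimws(substr(hdr, 245, 252)))
  ns <- as.integer(trimws(substr(hdr, 253, 256)))
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  fld <- function(offset, width) {
    start <- offset * ns
    vapply(seq_len(ns) - 1, function(i)
      trimws(substr(sig_hdr, start + i * width + 1,
                    start + (i + 1) * width)), "")
  }
  labels <- fld(0, 16)
  phys_min <- as.numeric(fld(104, 8))
  phys_max <- as.numeric(fld(112, 8))
  dig_min <- as.numeric(fld(120, 8))
  dig_max <- as.numeric(fld(128, 8))
  spr <- as.integer(fld(216, 8))
  stopifnot(length(unique(spr)) == 1)
  samples <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, endian = "little")
      phys <- phys_min[ch] + (dig - dig_min[ch]) *
        (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
      samples[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <- phys
    }
  }
  parts <- strsplit(labels, "_")
  subject_id <- sub("^subj (\\S+).*", "\\1", patient)
  group <- if (grepl("grp case", patient)) "case" else "control"
  emg_recording(samples, spr[1] / dur,
                data.frame(muscle = vapply(parts, `[`, "", 1),
                           index = as.integer(vapply(parts, `[`, "", 2))),
                subject_id, group)
}

#' Write a cohort manifest as JSON
#'
#' @param cohort an `emg_cohort` from [simulate_cohort()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  jsonlite::write_json(cohort$manifest, path, dataframe = "rows",
                       digits = NA)
  invisible(path)
}

#' Write a feature table as CSV
#'
#' Metadata columns first, then one column per feature (full double
#' precision).
#'
#' @param table feature table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  cols <- lapply(table, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col))
  lines <- c(paste(names(table), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @param feature_names optional; recorded as the table's feature set
#'   (defaults to all columns after the five metadata columns).
#' @return data.frame.
#' @export
read_feature_table <- function(path, feature_names = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- c("subject_id", "group", "muscle", "channel_index", "segment_index")
  if (is.null(feature_names)) feature_names <- setdiff(names(tab), meta)
  attr(tab, "feature_names") <- feature_names
  tab
}
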