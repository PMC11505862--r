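# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

fs_std <- 2048

# A small epoch set built directly from a matrix (bypasses simulation).
toy_epoch_set <- function(x, fs = fs_std, subject = "s01",
                          group = "control", muscle = "ECR", channel = 1L) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  structure(list(
    x = x,
    info = data.frame(subject_id = subject, group = group, muscle = muscle,
                      channel_index = channel,
                      segment_index = seq_len(nrow(x)),
                      stringsAsFactors = FALSE),
    fs = fs), class = "epoch_set")
}

# Two-class Gaussian feature table with subject structure: each subject
# contributes `rows_per_subject` rows; class means differ by `delta` (in
# s.d. units) on every feature.
toy_feature_table <- function(n_subjects_per_class = 4, rows_per_subject = 50,
                              n_features = 2, delta = 6, seed = 1) {
  set.seed(seed)
  subj <- c(sprintf("p%02d", seq_len(n_subjects_per_class)),
            sprintf("s%02d", seq_len(n_subjects_per_class)))
  grp <- rep(c("case", "control"), each = n_subjects_per_class)
  rows <- do.call(rbind, lapply(seq_along(subj), function(i) {
    mu <- if (grp[i] == "case") delta else 0
    f <- matrix(rnorm(rows_per_subject * n_features, mu), rows_per_subject)
    colnames(f) <- sprintf("f%d", seq_len(n_features))
    cbind(data.frame(subject_id = subj[i], group = grp[i],
                     muscle = "ECR", channel_index = 1L,
                     segment_index = seq_len(rows_per_subject),
                     stringsAsFactors = FALSE), as.data.frame(f))
  }))
  attr(rows, "feature_names") <- sprintf("f%d", seq_len(n_features))
  rows
}

# A deterministic coupled test signal: pacing rhythm at f_p plus a carrier
# at f_a whose amplitude follows the rhythm's phase.
coupled_signal <- function(dur = 4, fs = fs_std, f_p = 10, f_a = 150) {
  t <- (seq_len(dur * fs) - 1) / fs
  cos(2 * pi * f_p * t) + (1 + cos(2 * pi * f_p * t)) * cos(2 * pi * f_a * t)
}

# Constant-logit network: every input maps to probability `p`.
constant_prob_model <- function(p, n_features, spec = fnn_spec()) {
  L <- spec$hidden_layers
  W <- c(list(matrix(0, spec$width, n_features)),
         rep(list(matrix(0, spec$width, spec$width)), L - 1),
         list(matrix(0, 1, spec$width)))
  b <- c(rep(list(numeric(spec$width)), L), list(log(p / (1 - p))))
  structure(list(W = W, b = b, spec = spec, train_acc = NA, val_acc = NA,
                 test_subject = NA), class = "fnn_model")
}
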