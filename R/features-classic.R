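# The sixteen classic time- and frequency-domain sEMG features, computed
# per 500 ms epoch. Scalar versions operate on one numeric vector;
# classic_features() evaluates all of them over an epoch_set, vectorised
# across epochs.

#' Root mean square amplitude
#'
#' @param x numeric vector of samples.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  if (!length(x)) stopf("rms: empty input")
  sqrt(mean(x^2))
}

#' v-order amplitude estimate
#'
#' Generalised mean amplitude `(mean(|x|^v))^(1/v)`; reduces to [rms()] at
#' `v = 2`. Absolute values are taken so fractional orders are defined for
#' negative samples.
#'
#' @param x numeric vector.
#' @param v positive order.
#' @export
v_order <- function(x, v = 2) {
  if (!is_scalar_num(v) || v <= 0) stopf("v must be positive")
  if (!length(x)) stopf("v_order: empty input")
  mean(abs(x)^v)^(1 / v)
}

#' Log detector
#'
#' Two conventions are provided. `"classical"` (default) is the geometric
#' mean of `|x|`: `exp(mean(ln |x|))`, the form used throughout the EMG
#' feature literature. `"base10"` keeps the literal mixed-base reading of
#' the printed formula, `e^(mean(log10 |x|))`. Zero samples are floored at
#' machine epsilon.
#'
#' @param x numeric vector.
#' @param base_mode `"classical"` or `"base10"`.
#' @export
log_detector <- function(x, base_mode = c("classical", "base10")) {
  base_mode <- match.arg(base_mode)
  if (!length(x)) stopf("log_detector: empty input")
  ax <- pmax(abs(x), .Machine$double.eps)
  if (base_mode == "classical") exp(mean(log(ax))) else exp(mean(log10(ax)))
}

#' Mean absolute value
#'
#' @param x numeric vector.
#' @export
mav <- function(x) {
  if (!length(x)) stopf("mav: empty input")
  mean(abs(x))
}

#' Threshold-based counting features
#'
#' * `MYOP`: fraction of samples with `|x| >= threshold` (myopulse rate).
#' * `ZC`: zero crossings whose adjacent-sample difference also clears the
#'   threshold (noise-gated sign changes).
#' * `SSC`: slope sign changes, counted when the product of adjacent slopes
#'   reaches the threshold.
#' * `WAMP`: Willison amplitude, adjacent-sample differences of at least
#'   the threshold.
#'
#' @param x numeric vector (length >= 3 for SSC).
#' @param threshold amplitude threshold, in raw signal units.
#' @return Named list with MYOP, ZC, SSC, WAMP.
#' @export
threshold_counts <- function(x, threshold = 0.01) {
  if (threshold < 0) stopf("threshold must be >= 0")
  n <- length(x)
  if (n < 3) stopf("threshold_counts: need at least 3 samples")
  d <- diff(x)
  myop <- mean(abs(x) >= threshold)
  zc <- sum(x[-n] * x[-1] < 0 & abs(d) >= threshold)
  ssc <- sum((x[2:(n - 1)] - x[1:(n - 2)]) * (x[2:(n - 1)] - x[3:n]) >=
               threshold)
  wamp <- sum(abs(d) >= threshold)
  list(MYOP = myop, ZC = as.integer(zc), SSC = as.integer(ssc),
       WAMP = as.integer(wamp))
}

#' Absolute temporal moments of order 3, 4 and 5
#'
#' @param x numeric vector.
#' @return Named list with TM3 = |mean(x^3)|, TM4 = mean(x^4),
#'   TM5 = |mean(x^5)|.
#' @export
temporal_moments <- function(x) {
  if (!length(x)) stopf("temporal_moments: empty input")
  list(TM3 = abs(mean(x^3)), TM4 = mean(x^4), TM5 = abs(mean(x^5)))
}

#' Waveform length, DASDV and square integral
#'
#' @param x numeric vector (length >= 2).
#' @return Named list: `WL` (total variation), `DASDV` (RMS of the first
#'   difference) and `SI` (signal energy, `sum(x^2) = N * RMS^2`).
#' @export
waveform_measures <- function(x) {
  if (length(x) < 2) stopf("waveform_measures: need at least 2 samples")
  d <- diff(x)
  list(WL = sum(abs(d)), DASDV = sqrt(mean(d^2)), SI = sum(x^2))
}

#' Mean and median frequency from the periodogram
#'
#' One-sided periodogram with the DC bin excluded. `MNF` is the
#' power-weighted mean frequency; `MDF` is the first frequency bin at which
#' cumulative power reaches half the total.
#'
#' @param x numeric vector (length >= 8).
#' @param fs sampling rate in Hz.
#' @return Named list with MNF and MDF in Hz.
#' @export
spectral_features <- function(x, fs) {
  n <- length(x)
  if (n < 8) stopf("spectral_features: need at least 8 samples")
  if (all(x == 0)) stopf("spectral_features: all-zero signal has no spectrum")
  X <- fft(x)
  half <- floor(n / 2)
  P <- Mod(X[2:(half + 1)])^2
  f <- (1:half) * fs / n
  tot <- sum(P)
  mnf <- sum(f * P) / tot
  mdf <- f[which(cumsum(P) >= tot / 2)[1]]
  list(MNF = mnf, MDF = mdf)
}

classic_feature_names <- c("RMS", "V", "LOG", "MAV", "MYOP", "ZC", "SSC",
                           "WAMP", "TM3", "TM4", "TM5", "WL", "DASDV", "SI",
                           "MNF", "MDF")

#' Classic feature table for an epoch set
#'
#' Computes the sixteen classic features for every epoch, vectorised across
#' rows. Returns the epoch metadata columns followed by one column per
#' feature.
#'
#' @param epochs an `epoch_set` from [segment_epochs()] / [bind_epochs()].
#' @param threshold amplitude threshold for MYOP/ZC/SSC/WAMP.
#' @param v order of the v-order feature (recorded in
#'   `attr(, "v_order")`).
#' @param log_mode convention for the log detector, see [log_detector()].
#' @return data.frame (a feature table).
#' @export
classic_features <- function(epochs, threshold = 0.01, v = 2,
                             log_mode = "classical") {
  stopifnot(inherits(epochs, "epoch_set"))
  x <- epochs$x
  n <- ncol(x)
  ax <- abs(x)
  d <- x[, -1, drop = FALSE] - x[, -n, drop = FALSE]
  RMS <- sqrt(rowMeans(x^2))
  V <- rowMeans(ax^v)^(1 / v)
  axf <- pmax(ax, .Machine$double.eps)
  LOG <- if (log_mode == "classical") exp(rowMeans(log(axf)))
         else exp(rowMeans(log10(axf)))
  MAV <- rowMeans(ax)
  MYOP <- rowMeans(ax >= threshold)
  ZC <- rowSums(x[, -n, drop = FALSE] * x[, -1, drop = FALSE] < 0 &
                  abs(d) >= threshold)
  mid <- x[, 2:(n - 1), drop = FALSE]
  SSC <- rowSums((mid - x[, 1:(n - 2), drop = FALSE]) *
                   (mid - x[, 3:n, drop = FALSE]) >= threshold)
  WAMP <- rowSums(abs(d) >= threshold)
  TM3 <- abs(rowMeans(x^3)); TM4 <- rowMeans(x^4); TM5 <- abs(rowMeans(x^5))
  WL <- rowSums(abs(d))
  DASDV <- sqrt(rowMeans(d^2))
  SI <- rowSums(x^2)
  # one-sided periodogram, DC excluded, per epoch
  X <- mvfft(t(x))
  half <- floor(n / 2)
  P <- Mod(X[2:(half + 1), , drop = FALSE])^2
  f <- (1:half) * epochs$fs / n
  tot <- colSums(P)
  if (any(tot == 0)) stopf("classic_features: all-zero epoch has no spectrum")
  MNF <- colSums(f * P) / tot
  MDF <- f[max.col(t(apply(P, 2, cumsum) >= rep(tot / 2, each = half)),
                   ties.method = "first")]
  out <- cbind(epochs$info,
               data.frame(RMS = RMS, V = V, LOG = LOG, MAV = MAV, MYOP = MYOP,
                          ZC = ZC, SSC = SSC, WAMP = WAMP, TM3 = TM3,
                          TM4 = TM4, TM5 = TM5, WL = WL, DASDV = DASDV,
                          SI = SI, MNF = MNF, MDF = MDF))
  attr(out, "v_order") <- v
  attr(out, "feature_names") <- classic_feature_names
  out
}
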