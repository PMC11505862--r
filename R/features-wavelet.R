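# Orthogonal Daubechies-4 (four vanishing moments, 8-tap) discrete wavelet
# transform with periodized boundary handling, and per-subband summary
# features. Periodization keeps the transform exactly orthogonal, so signal
# energy equals total coefficient energy and the inverse is the transpose.

# db4 analysis scaling (low-pass) filter, unit L2 norm.
DB4_LO <- c(-0.010597401784997278, 0.032883011666982945,
            0.030841381835986965, -0.18703481171888114,
            -0.027983769416983850, 0.63088076792959040,
            0.71484657055254150, 0.23037781330885523)
# Quadrature-mirror high-pass: g[k] = (-1)^k h[L-1-k]
DB4_HI <- rev(DB4_LO) * c(1, -1, 1, -1, 1, -1, 1, -1)

dwt_step <- function(x, h, g) {
  n <- length(x)
  half <- n / 2
  a <- numeric(half); d <- numeric(half)
  for (m in seq_along(h)) {
    idx <- ((m - 1 + 2 * (seq_len(half) - 1)) %% n) + 1
    a <- a + h[m] * x[idx]
    d <- d + g[m] * x[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, h, g) {
  half <- length(a)
  n <- 2 * half
  x <- numeric(n)
  for (m in seq_along(h)) {
    idx <- ((m - 1 + 2 * (seq_len(half) - 1)) %% n) + 1
    x[idx] <- x[idx] + h[m] * a + g[m] * d
  }
  x
}

#' Periodized db4 wavelet decomposition
#'
#' Decomposes a signal with the 8-tap Daubechies wavelet (four vanishing
#' moments) down to `level`, using circular (periodized) boundary handling.
#' The transform is orthogonal: coefficient energy equals signal energy and
#' [idwt_db4()] reconstructs exactly. At 2048 Hz and level 4 the dyadic
#' subbands are approximately A4 0-64, D4 64-128, D3 128-256, D2 256-512
#' and D1 512-1024 Hz.
#'
#' @param x numeric vector; its length must be divisible by `2^level`.
#' @param level decomposition depth (default 4).
#' @return List of class `wavelet_decomposition` with coefficient vectors
#'   `A4` (approximation at the deepest level, named for the default depth)
#'   and `D1` ... `D<level>`, plus `level` and `n`.
#' @export
dwt_db4 <- function(x, level = 4) {
  n <- length(x)
  if (n < 2^level || n %% 2^level != 0)
    stopf("dwt_db4: length %d not divisible by 2^%d", n, level)
  details <- vector("list", level)
  cur <- x
  for (l in seq_len(level)) {
    st <- dwt_step(cur, DB4_LO, DB4_HI)
    details[[l]] <- st$d
    cur <- st$a
  }
  out <- c(list(cur), rev(details))
  names(out) <- c(paste0("A", level), paste0("D", level:1))
  structure(c(out, list(level = level, n = n)),
            class = "wavelet_decomposition")
}

#' Inverse periodized db4 transform
#'
#' @param dec a `wavelet_decomposition` from [dwt_db4()].
#' @return The reconstructed signal.
#' @export
idwt_db4 <- function(dec) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  level <- dec$level
  cur <- dec[[paste0("A", level)]]
  for (l in level:1)
    cur <- idwt_step(cur, dec[[paste0("D", l)]], DB4_LO, DB4_HI)
  cur
}

wavelet_band_names <- function(level = 4) c(paste0("A", level), paste0("D", level:1))

#' Subband summary features from a wavelet decomposition
#'
#' The scalar taken from each subband's coefficients is configurable; RMS
#' and MAV of the coefficients are the defaults, applied uniformly to the
#' five subbands in the fixed order A4, D4, D3, D2, D1.
#'
#' @param dec a `wavelet_decomposition`.
#' @param stats character vector among `"RMS"`, `"MAV"`, `"SD"`, `"ENERGY"`.
#' @return Named numeric vector, names `WT_<band>_<stat>`.
#' @export
wavelet_features <- function(dec, stats = c("RMS", "MAV")) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  known <- c(RMS = function(v) sqrt(mean(v^2)),
             MAV = function(v) mean(abs(v)),
             SD = function(v) sd(v),
             ENERGY = function(v) sum(v^2))
  bad <- setdiff(stats, names(known))
  if (length(bad)) stopf("unknown subband statistic: %s",
                         paste(bad, collapse = ", "))
  bands <- wavelet_band_names(dec$level)
  out <- numeric(0)
  for (b in bands) for (s in stats) {
    out <- c(out, setNames(known[[s]](dec[[b]]), paste0("WT_", b, "_", s)))
  }
  out
}

#' Wavelet feature table for an epoch set
#'
#' Runs the periodized db4 decomposition on every epoch (vectorised across
#' rows) and summarises each subband with the requested statistics.
#'
#' @param epochs an `epoch_set`.
#' @param level decomposition depth.
#' @param stats subband statistics, see [wavelet_features()].
#' @return data.frame feature table with columns `WT_<band>_<stat>`.
#' @export
wavelet_feature_table <- function(epochs, level = 4, stats = c("RMS", "MAV")) {
  stopifnot(inherits(epochs, "epoch_set"))
  x <- epochs$x
  n <- ncol(x)
  if (n %% 2^level != 0)
    stopf("epoch length %d not divisible by 2^%d", n, level)
  # matrix form of dwt_step across epochs (rows)
  bands <- list()
  cur <- x
  for (l in seq_len(level)) {
    nn <- ncol(cur); half <- nn / 2
    a <- matrix(0, nrow(cur), half); d <- a
    for (m in seq_along(DB4_LO)) {
      idx <- ((m - 1 + 2 * (seq_len(half) - 1)) %% nn) + 1
      a <- a + DB4_LO[m] * cur[, idx, drop = FALSE]
      d <- d + DB4_HI[m] * cur[, idx, drop = FALSE]
    }
    bands[[paste0("D", l)]] <- d
    cur <- a
  }
  bands[[paste0("A", level)]] <- cur
  known <- c(RMS = function(v) sqrt(rowMeans(v^2)),
             MAV = function(v) rowMeans(abs(v)),
             SD = function(v) apply(v, 1, sd),
             ENERGY = function(v) rowSums(v^2))
  bad <- setdiff(stats, names(known))
  if (length(bad)) stopf("unknown subband statistic: %s",
                         paste(bad, collapse = ", "))
  cols <- list()
  for (b in wavelet_band_names(level)) for (s in stats)
    cols[[paste0("WT_", b, "_", s)]] <- known[[s]](bands[[b]])
  out <- cbind(epochs$info, as.data.frame(cols))
  attr(out, "feature_names") <- names(cols)
  out
}
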