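#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nyquist frequency of a sampling interval
#'
#' @param tr_seconds sampling interval in seconds.
#' @return Frequency in Hz.
#' @keywords internal
nyquist_hz <- function(tr_seconds) 1 / (2 * tr_seconds)

#' Alias of a frequency under regular sampling
#'
#' Folds a (possibly supra-Nyquist) frequency into the principal band
#' `[0, fs/2]` of a sampling rate: the apparent frequency is
#' `min_k |f - k * fs|`.  A 1 Hz cardiac rhythm sampled at TR = 0.5 s
#' (fs = 2 Hz) sits exactly at Nyquist; decimated to TR = 1 s it folds to
#' 0 Hz.
#'
#' @param freq_hz true frequency in Hz.
#' @param fs_hz sampling rate in Hz.
#' @return Apparent (aliased) frequency in Hz, in `[0, fs/2]`.
#' @export
alias_frequency <- function(freq_hz, fs_hz) {
  stopifnot(freq_hz >= 0, fs_hz > 0)
  f <- freq_hz %% fs_hz
  pmin(f, fs_hz - f)
}

# Periodogram power of a series at the DFT frequencies (no taper).
# Returns list(freq, power) for the one-sided grid excluding DC.
periodogram <- function(x, dt) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  nf <- floor(n / 2)
  list(freq = (1:nf) / (n * dt), power = sp[2:(nf + 1)])
}

# Fraction of (non-DC) periodogram power inside [lo, hi].
band_power_fraction <- function(x, dt, lo, hi) {
  pg <- periodogram(x, dt)
  tot <- sum(pg$power)
  if (tot == 0) return(0)
  sum(pg$power[pg$freq >= lo & pg$freq <= hi]) / tot
}

# z-score a vector; constant input maps to zeros.
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x * 0)
  (x - mean(x)) / s
}

# Columnwise Pearson correlation of matrix columns with a single vector,
# without the per-call overhead of cor().
colcor <- function(X, y) {
  Xc <- sweep(X, 2L, colMeans(X))
  yc <- y - mean(y)
  num <- as.vector(crossprod(Xc, yc))
  den <- sqrt(colSums(Xc^2) * sum(yc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Index helper: logical 3D mask -> integer voxel indices (column-major).
mask_idx <- function(mask) which(as.logical(mask))

# Assemble a flat in-mask vector back into a 3D array (0 elsewhere).
unmask <- function(values, mask, fill = 0) {
  out <- array(fill, dim = dim(mask))
  out[mask_idx(mask)] <- values
  out
}
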