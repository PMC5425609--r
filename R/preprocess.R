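#' BOLD run container
#'
#' A 4D intensity grid with its repetition time, brain mask and provenance.
#'
#' @param data 4D numeric array (X x Y x Z x T, T >= 2).
#' @param tr_seconds repetition time, seconds.
#' @param brain_mask logical 3D array matching the spatial grid.
#' @param meta named list of provenance labels (subject, session, run,
#'   processing history).
#' @return A `bold_run` object.
#' @export
bold_run <- function(data, tr_seconds, brain_mask, meta = list()) {
  d <- dim(data)
  if (length(d) != 4 || d[4] < 2) stop("data must be X x Y x Z x T with T >= 2")
  if (!identical(dim(brain_mask), d[1:3])) stop("mask/grid shape mismatch")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  brain_mask <- array(as.logical(brain_mask), d[1:3])
  mdat <- matrix(data, prod(d[1:3]), d[4])[mask_idx(brain_mask), , drop = FALSE]
  if (!all(is.finite(mdat))) stop("non-finite values inside the brain mask")
  structure(list(data = data, tr_seconds = tr_seconds,
                 brain_mask = brain_mask, meta = meta),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold_run: %dx%dx%d grid, %d frames, TR %.3g s, %d mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr_seconds, sum(x$brain_mask)))
  if (length(x$meta$history))
    cat("  history:", paste(x$meta$history, collapse = " -> "), "\n")
  invisible(x)
}

# In-mask voxel series as a T x V matrix.
run_matrix <- function(run) {
  d <- dim(run$data)
  t(matrix(run$data, prod(d[1:3]), d[4])[mask_idx(run$brain_mask), ,
                                          drop = FALSE])
}

# Rebuild a bold_run from a T x V in-mask matrix (out-of-mask voxels zero).
run_from_matrix <- function(X, run, note = NULL) {
  d <- dim(run$data)
  flat <- matrix(0, prod(d[1:3]), nrow(X))
  flat[mask_idx(run$brain_mask), ] <- t(X)
  meta <- run$meta
  if (!is.null(note)) meta$history <- c(meta$history, note)
  bold_run(array(flat, c(d[1:3], nrow(X))), run$tr_seconds, run$brain_mask,
           meta)
}

#' Zero-phase temporal band-pass filtering
#'
#' Filters every in-mask voxel series to the requested band by Fourier-domain
#' masking, which is zero-phase by construction: no time shift is introduced,
#' so downstream lag estimates are unbiased by the filter.  A high-pass at
#' 0.008 Hz removes slow drifts; the lag-mapping pipeline uses the wider
#' band-pass 0.008–0.16 Hz.
#'
#' @param run a [bold_run()].
#' @param low_hz high-pass edge in Hz, or `NULL` for none.
#' @param high_hz low-pass edge in Hz, or `NULL` for none.
#' @return Filtered [bold_run()].  The temporal mean is removed whenever a
#'   high-pass edge is given (DC lies below any positive cutoff).
#' @export
temporal_filter <- function(run, low_hz = 0.008, high_hz = NULL) {
  nyq <- nyquist_hz(run$tr_seconds)
  lo <- low_hz %||% 0
  hi <- high_hz %||% nyq
  if (lo < 0 || hi <= lo || (!is.null(high_hz) && high_hz >= nyq))
    stop("filter band must satisfy 0 <= low < high < Nyquist (",
         signif(nyq, 3), " Hz)")
  Y <- fft_bandpass(run_matrix(run), run$tr_seconds, low_hz, high_hz)
  run_from_matrix(Y, run, note = sprintf("bandpass[%g,%g]", lo,
                                         if (is.null(high_hz)) NA else hi))
}

# Zero-phase Fourier-domain band-pass of a vector or T x V matrix.
fft_bandpass <- function(X, tr_seconds, low_hz = NULL, high_hz = NULL) {
  vec_in <- is.null(dim(X))
  if (vec_in) X <- matrix(X, ncol = 1)
  lo <- low_hz %||% 0
  hi <- high_hz %||% nyquist_hz(tr_seconds)
  n <- nrow(X)
  freq <- (seq_len(n) - 1) / (n * tr_seconds)
  freq <- pmin(freq, 1 / tr_seconds - freq)
  keep <- freq >= lo & freq <= hi
  keep[1] <- lo <= 0
  F <- stats::mvfft(X)
  F[!keep, ] <- 0
  Y <- Re(stats::mvfft(F, inverse = TRUE)) / n
  if (vec_in) Y[, 1] else Y
}

#' Discard, normalize and concatenate runs
#'
#' Drops the initial transition frames of each run, normalizes every in-mask
#' voxel of every run to zero mean and unit variance, then concatenates the
#' runs in the given order (the standard preparation before lag or
#' connectivity mapping across runs).
#'
#' @param runs list of [bold_run()] sharing grid, TR and mask.
#' @param discard_volumes number of initial frames dropped per run.
#' @return Concatenated [bold_run()] with `sum(T_i - discard)` frames.
#'   Zero-variance in-mask voxels are flagged (attribute `flat_voxels`) and
#'   set to a zero series.
#' @export
normalize_concat <- function(runs, discard_volumes = 20L) {
  if (inherits(runs, "bold_run")) runs <- list(runs)
  stopifnot(length(runs) >= 1)
  ref <- runs[[1]]
  segs <- vector("list", length(runs))
  nflat <- 0
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    if (!identical(dim(r$data)[1:3], dim(ref$data)[1:3]) ||
        !identical(r$brain_mask, ref$brain_mask) ||
        r$tr_seconds != ref$tr_seconds)
      stop("runs must share grid, TR and brain mask")
    nt <- dim(r$data)[4]
    if (discard_volumes >= nt) stop("discard_volumes >= run length")
    X <- run_matrix(r)[(discard_volumes + 1):nt, , drop = FALSE]
    X <- sweep(X, 2L, colMeans(X))
    sds <- sqrt(colSums(X^2) / (nrow(X) - 1))
    flat <- sds == 0
    nflat <- nflat + sum(flat)
    sds[flat] <- 1
    segs[[i]] <- sweep(X, 2L, sds, `/`)
  }
  out <- run_from_matrix(do.call(rbind, segs), ref,
                         note = sprintf("discard%d+znorm+concat%d",
                                        discard_volumes, length(runs)))
  attr(out, "flat_voxels") <- nflat
  if (nflat > 0)
    warning(nflat, " zero-variance in-mask voxel series set to zero")
  out
}

#' Temporal decimation without anti-alias filtering
#'
#' Keeps every `factor`-th frame starting at `offset` and multiplies the
#' repetition time accordingly.  Deliberately applies no low-pass filter
#' first: physiological rhythms above the new Nyquist frequency fold into
#' the low-frequency band, which is the aliasing mechanism the sampling-rate
#' experiments probe.
#'
#' @param run a [bold_run()].
#' @param factor positive integer decimation factor.
#' @param offset first retained frame, 0-based (default 0).
#' @return Decimated [bold_run()] with `tr_seconds * factor`.
#' @export
decimate_run <- function(run, factor, offset = 0L) {
  factor <- as.integer(factor)
  nt <- dim(run$data)[4]
  if (factor < 1) stop("factor must be >= 1")
  if (factor >= nt) stop("factor must be smaller than the number of frames")
  keep <- seq(1L + offset, nt, by = factor)
  out <- run
  out$data <- run$data[, , , keep, drop = FALSE]
  out$tr_seconds <- run$tr_seconds * factor
  out$meta$history <- c(run$meta$history, sprintf("decimate%d", factor))
  out
}
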