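#' Lag map container
#'
#' A 3D map of arrival-time offsets in seconds on the discrete grid
#' `{k * TR}`.  Polarity contract: positive = upstream (earlier arrival of
#' the circulating sLFO waveform relative to the reference).
#'
#' @param values 3D array of seconds.
#' @param valid_mask logical 3D array; invalid voxels are excluded from all
#'   statistics.
#' @param method `"sss"` or `"rec"`.
#' @param tr_seconds grid step in seconds.
#' @param shift_range_s two reals, the search range.
#' @return A `lag_map` object.
#' @export
lag_map <- function(values, valid_mask, method, tr_seconds, shift_range_s) {
  stopifnot(identical(dim(values), dim(valid_mask)))
  structure(list(values = values, valid_mask = valid_mask, method = method,
                 polarity = "positive = upstream / earlier arrival",
                 tr_seconds = tr_seconds, shift_range_s = shift_range_s),
            class = "lag_map")
}

#' @export
print.lag_map <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf(
    "lag_map [%s]: %d valid voxels, range %.2g..%.2g s (grid %.2g s); %s\n",
    x$method, length(v), min(v), max(v), x$tr_seconds, x$polarity))
  invisible(x)
}

#' Shifted cross-correlation (cross-correlogram)
#'
#' For each integer frame shift `s`, the Pearson correlation between each
#' voxel series and the reference advanced by `s` frames, computed over the
#' overlapping segment only (no padding).  A voxel whose series leads the
#' reference by `d` frames peaks at `s = +d` — the positive-upstream
#' polarity contract.
#'
#' @param voxel_series numeric vector, or T x V matrix of series in columns.
#' @param reference numeric vector of length T.
#' @param shifts integer frame shifts.
#' @param min_overlap shifts whose overlap is shorter are marked `NA`.
#' @return Matrix of correlations, `length(shifts)` x V (a vector input
#'   yields a named vector).
#' @export
lagged_correlogram <- function(voxel_series, reference, shifts,
                               min_overlap = 10L) {
  vec_in <- is.null(dim(voxel_series))
  X <- if (vec_in) matrix(voxel_series, ncol = 1) else voxel_series
  nT <- nrow(X)
  stopifnot(length(reference) == nT)
  out <- matrix(NA_real_, length(shifts), ncol(X))
  for (i in seq_along(shifts)) {
    s <- shifts[i]
    if (abs(s) > nT - 2) next
    if (s >= 0) {
      xx <- X[seq_len(nT - s), , drop = FALSE]
      rr <- reference[(1 + s):nT]
    } else {
      xx <- X[(1 - s):nT, , drop = FALSE]
      rr <- reference[seq_len(nT + s)]
    }
    if (length(rr) < min_overlap) next
    out[i, ] <- colcor(xx, rr)
  }
  rownames(out) <- shifts
  if (vec_in) out[, 1] else out
}

#' Lag mapping against a sinus seed (Lag-SSS)
#'
#' The mean series over an ROI on the descending superior sagittal sinus
#' (the most downstream reference) is cross-correlated with every in-mask
#' voxel over a discrete shift grid (default -4..+6 s at TR steps); each
#' voxel's lag is the shift maximizing the correlation (3D time x voxel x
#' shift search, argmax along shift).  Ties break toward the smallest
#' absolute shift (toward the null rather than the range edge).  The map is
#' then spatially smoothed (default 8 mm FWHM) with invalid voxels excluded
#' from the kernel average.
#'
#' @param run a [bold_run()].
#' @param sss_roi a [roi_mask()] (or logical 3D array) on the sinus.
#' @param shift_range_s search range in seconds (default `c(-4, 6)`).
#' @param fwhm_mm lag-map smoothing kernel; 0 disables smoothing.
#' @param voxel_size_mm voxel size for the kernel.
#' @param min_overlap minimum overlapping frames per shift.
#' @return A [lag_map()] (method `"sss"`).
#' @export
lag_sss <- function(run, sss_roi, shift_range_s = c(-4, 6), fwhm_mm = 8,
                    voxel_size_mm = c(4, 4, 4), min_overlap = 10L) {
  roi <- if (inherits(sss_roi, "roi_mask")) sss_roi$mask else sss_roi
  if (!any(roi)) stop("empty sinus ROI")
  tr <- run$tr_seconds
  X <- run_matrix(run)
  vox <- mask_idx(run$brain_mask)
  roi_cols <- which(vox %in% which(roi))
  if (!length(roi_cols)) stop("sinus ROI lies outside the brain mask")
  reference <- rowMeans(X[, roi_cols, drop = FALSE])
  if (stats::sd(reference) == 0) stop("flat reference time course")
  shifts <- seq(round(shift_range_s[1] / tr), round(shift_range_s[2] / tr))
  C <- lagged_correlogram(X, reference, shifts, min_overlap)
  ord <- order(abs(shifts))        # tie-break: smallest |shift| wins
  Cord <- C[ord, , drop = FALSE]
  Cord[is.na(Cord)] <- -Inf
  best <- max.col(t(Cord), ties.method = "first")
  lag_vals <- shifts[ord][best] * tr
  valid_in <- apply(C, 2L, function(col) any(is.finite(col)))
  values <- unmask(lag_vals, run$brain_mask)
  valid <- unmask(valid_in, run$brain_mask, fill = FALSE) & run$brain_mask
  if (fwhm_mm > 0)
    values <- smooth_gaussian3d(values, fwhm_mm, voxel_size_mm, mask = valid)
  lag_map(values, valid, "sss", tr, shift_range_s)
}

# correlogram around a target shift; TRUE where a strict local peak at
# `target` meets the threshold (one-sided at window endpoints).
local_peak_at <- function(C, shifts, target, threshold) {
  i <- match(target, shifts)
  v <- C[i, ]
  ok <- is.finite(v) & v >= threshold
  for (nb in c(i - 1L, i + 1L)) {
    if (nb >= 1L && nb <= length(shifts)) {
      w <- C[nb, ]
      ok <- ok & (!is.finite(w) | v > w)
    }
  }
  ok
}

#' Recursive seed-tracking lag mapping (Lag-rec)
#'
#' The initial seed is the set of voxels whose cross-correlogram against the
#' global mean signal peaks at zero shift with a peak of at least
#' `peak_threshold`; they are assigned lag 0.  The reference is then updated
#' recursively: at each step, unassigned voxels whose correlogram against
#' the current seed's mean series has a local peak at +TR (upstream
#' direction) or -TR (downstream) meeting the threshold are assigned that
#' lag and become the new seed, up to `max_lag_s` in both directions.
#' Correlogram peaks below the threshold are discarded, so some voxels
#' remain unassigned ("holes", see [fill_holes()]).  Voxels are assigned at
#' most once, tracking outward from zero.
#'
#' @param run a [bold_run()].
#' @param max_lag_s tracking range in seconds (default 4, both directions).
#' @param peak_threshold minimum correlogram peak (default 0.2).
#' @param min_overlap minimum overlapping frames per shift.
#' @return List: `map` (a [lag_map()], method `"rec"`) and `seed_traces`, a
#'   data frame per lag step with the member-voxel count, the mean-series
#'   amplitude (its standard deviation), and the mean series itself in the
#'   list column `mean_series` — the recursively defined reference
#'   waveforms.
#' @export
lag_rec <- function(run, max_lag_s = 4, peak_threshold = 0.2,
                    min_overlap = 10L) {
  tr <- run$tr_seconds
  n_steps <- round(max_lag_s / tr)
  X <- run_matrix(run)
  nv <- ncol(X)
  global <- rowMeans(X)
  if (stats::sd(global) == 0) stop("flat global mean signal")
  win <- -2:2
  C0 <- lagged_correlogram(X, global, win, min_overlap)
  seed0 <- which(local_peak_at(C0, win, 0L, peak_threshold))
  if (!length(seed0)) stop("empty initial seed")
  assigned <- rep(NA_real_, nv)
  assigned[seed0] <- 0
  traces <- list(make_trace(0, X[, seed0, drop = FALSE]))
  for (dir in c(1L, -1L)) {
    seed <- seed0
    for (j in seq_len(n_steps)) {
      ref <- rowMeans(X[, seed, drop = FALSE])
      if (stats::sd(ref) == 0) break
      cand <- which(is.na(assigned))
      if (!length(cand)) break
      Cc <- lagged_correlogram(X[, cand, drop = FALSE], ref, win, min_overlap)
      hit <- cand[local_peak_at(Cc, win, dir, peak_threshold)]
      if (!length(hit)) break
      assigned[hit] <- dir * j * tr
      seed <- hit
      traces[[length(traces) + 1L]] <-
        make_trace(dir * j * tr, X[, hit, drop = FALSE])
    }
  }
  valid_in <- !is.na(assigned)
  vals <- assigned
  vals[!valid_in] <- 0
  values <- unmask(vals, run$brain_mask)
  valid <- unmask(valid_in, run$brain_mask, fill = FALSE) & run$brain_mask
  st <- do.call(rbind, lapply(traces, function(t0)
    data.frame(lag_seconds = t0$lag, n_voxels = t0$n, amplitude = t0$amp)))
  st <- st[order(st$lag_seconds), ]
  st$mean_series <- lapply(traces[order(vapply(traces, `[[`, 0, "lag"))],
                           `[[`, "tc")
  rownames(st) <- NULL
  list(map = lag_map(values, valid, "rec", tr, c(-max_lag_s, max_lag_s)),
       seed_traces = st)
}

make_trace <- function(lag, Xseed) {
  tc <- rowMeans(Xseed)
  list(lag = lag, n = ncol(Xseed), amp = stats::sd(tc), tc = tc)
}

#' Fill unassigned lag-map voxels by Laplace interpolation
#'
#' Invalid in-mask voxels (correlogram holes) are filled by solving the
#' Laplace equation with the valid voxels as Dirichlet boundary, by
#' iterative relaxation: each hole relaxes to the mean of its 6-neighbours,
#' using only axes along which both neighbours are available (one-sided
#' axes are dropped so affine fields are reproduced exactly; an isolated
#' corner voxel falls back to all available neighbours).  Valid voxels are
#' never altered, and filled values obey the maximum principle (they stay
#' within the range of the surrounding valid values).
#'
#' @param map a [lag_map()].
#' @param mask optional logical 3D array limiting the domain (defaults to
#'   valid plus invalid-hole voxels, i.e. the map's full grid support where
#'   `valid_mask` is defined); holes are the in-mask invalid voxels.
#' @param tol relaxation stopping tolerance (max absolute update).
#' @param max_iter iteration cap.
#' @return A [lag_map()] with all in-mask voxels valid.
#' @export
fill_holes <- function(map, mask = NULL, tol = 1e-10, max_iter = 20000L) {
  if (is.null(mask)) mask <- array(TRUE, dim(map$values))
  valid <- map$valid_mask & mask
  if (!any(valid)) stop("no valid voxels to interpolate from")
  holes <- mask & !valid
  if (!any(holes)) return(map)
  d <- dim(map$values)
  vals <- map$values
  vals[holes] <- mean(vals[valid])
  hidx <- which(holes)
  hc <- arrayInd(hidx, d)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  nb <- matrix(NA_integer_, length(hidx), 6)
  for (k in 1:6) {
    cc <- sweep(hc, 2, offs[k, ], `+`)
    ok <- cc[, 1] >= 1 & cc[, 1] <= d[1] & cc[, 2] >= 1 & cc[, 2] <= d[2] &
      cc[, 3] >= 1 & cc[, 3] <= d[3]
    ii <- rep(NA_integer_, length(hidx))
    ii[ok] <- cc[ok, 1] + (cc[ok, 2] - 1) * d[1] + (cc[ok, 3] - 1) * d[1] * d[2]
    ii[!is.na(ii) & !mask[ifelse(is.na(ii), 1L, ii)]] <- NA_integer_
    nb[, k] <- ii
  }
  # keep an axis only when both its neighbours exist; else fall back
  use <- !is.na(nb)
  for (ax in 1:3) {
    a <- 2 * ax - 1; b <- 2 * ax
    pair <- use[, a] & use[, b]
    use[!pair, a] <- FALSE
    use[!pair, b] <- FALSE
  }
  none <- rowSums(use) == 0
  use[none, ] <- !is.na(nb[none, , drop = FALSE])
  if (any(rowSums(use) == 0)) stop("hole voxel with no in-mask neighbours")
  nbv <- nb
  nbv[!use] <- NA_integer_
  for (it in seq_len(max_iter)) {
    vm <- matrix(vals[nbv], nrow(nbv), 6)
    new <- rowMeans(vm, na.rm = TRUE)
    delta <- max(abs(new - vals[hidx]))
    vals[hidx] <- new
    if (delta < tol) break
  }
  out <- map
  out$values <- vals
  out$valid_mask <- valid | holes
  out
}

#' Compare two lag maps voxel by voxel
#'
#' @param a,b [lag_map()] objects on the same grid.
#' @param mask optional additional logical 3D restriction.
#' @return List: `correlation` (Pearson, over jointly valid voxels),
#'   `difference` (vector of `a - b`), `histogram` (a [hist()] object of the
#'   difference, breaks at half-TR grid steps), `n` voxels compared.
#' @export
compare_lag_maps <- function(a, b, mask = NULL) {
  stopifnot(identical(dim(a$values), dim(b$values)))
  joint <- a$valid_mask & b$valid_mask
  if (!is.null(mask)) joint <- joint & mask
  if (!any(joint)) stop("no jointly valid voxels")
  va <- a$values[joint]; vb <- b$values[joint]
  diffs <- va - vb
  tr <- a$tr_seconds
  br <- seq(floor(min(diffs) / tr) * tr - tr / 2,
            ceiling(max(diffs) / tr) * tr + tr / 2, by = tr)
  r <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    if (max(abs(diffs - diffs[1])) < 1e-12) 1 else NA_real_
  } else stats::cor(va, vb)
  list(correlation = r, difference = diffs,
       histogram = graphics::hist(diffs, breaks = br, plot = FALSE),
       n = sum(joint))
}

#' Recovery statistics of an estimated lag map against planted truth
#'
#' A lag map is only defined up to its reference's own lag: Lag-SSS is
#' anchored to the sinus seed, Lag-rec to the global-signal phase.  Before
#' voxelwise error is computed the estimate can therefore be aligned to the
#' truth by the median offset, rounded to the TR grid (`align = "median"`,
#' appropriate for Lag-rec); `align = "none"` compares as-is.
#'
#' @param map a [lag_map()].
#' @param truth_field 3D array of planted lags (seconds).
#' @param mask optional logical 3D restriction (defaults to valid voxels).
#' @param align `"none"` or `"median"`.
#' @return List: `offset` applied, `frac_exact` (match after rounding truth
#'   to the TR grid), `frac_within_tr` (|error| <= TR), `correlation`,
#'   `n` voxels.
#' @export
lag_truth_stats <- function(map, truth_field, mask = NULL,
                            align = c("none", "median")) {
  align <- match.arg(align)
  sel <- map$valid_mask
  if (!is.null(mask)) sel <- sel & mask
  est <- map$values[sel]
  tru <- truth_field[sel]
  tr <- map$tr_seconds
  offset <- 0
  if (align == "median")
    offset <- round(stats::median(tru - est) / tr) * tr
  est <- est + offset
  err <- est - tru
  list(offset = offset,
       frac_exact = mean(abs(est - round(tru / tr) * tr) < tr / 100),
       frac_within_tr = mean(abs(err) <= tr + 1e-9),
       correlation = if (stats::sd(est) > 0 && stats::sd(tru) > 0)
         stats::cor(est, tru) else NA_real_,
       n = length(est))
}
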