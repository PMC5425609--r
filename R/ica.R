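#' Spatial ICA decomposition of a BOLD run
#'
#' Decomposes the in-mask data into K spatially independent component maps
#' and their mixing time courses (spatial-ICA orientation: the independent
#' sources are the spatial maps, the mixing matrix gives the time courses),
#' via FastICA on a PCA-whitened basis.  Spatial maps are z-scored over
#' in-mask voxels.
#'
#' @param run a [bold_run()].
#' @param n_components number of components K (must be < T).
#' @param maxit,tol FastICA iteration controls.
#' @param seed RNG seed for the FastICA initial rotation.
#' @return A `component_set`: `spatial_maps` (K x V, z-scored), `time_courses`
#'   (T x K), `brain_mask`, `tr_seconds`, `explained_variance`, and empty
#'   feature/label slots to be filled by [compute_features()] and
#'   [classify_components()].
#' @export
decompose_ica <- function(run, n_components = 30L, maxit = 300L,
                          tol = 1e-6, seed = 1L) {
  X <- run_matrix(run)                      # T x V
  nt <- nrow(X); nv <- ncol(X)
  if (n_components >= nt) stop("n_components must be < number of frames")
  Xc <- sweep(X, 2L, colMeans(X))           # remove voxel means
  if (max(abs(Xc)) == 0) stop("degenerate (constant) data")
  Xc <- Xc - rowMeans(Xc)                   # and the per-frame spatial mean
  set.seed(seed)
  dec <- ica::icafast(t(Xc), nc = n_components, maxit = maxit, tol = tol)
  # dec$S: V x K independent spatial sources; dec$M: T x K mixing
  S_raw <- as.matrix(dec$S)                 # V x K spatial sources
  if (nrow(S_raw) != ncol(Xc)) S_raw <- t(S_raw)
  S_raw <- t(S_raw)                         # K x V
  A <- as.matrix(dec$M)                     # T x K time courses
  if (nrow(A) != nrow(Xc)) A <- t(A)
  ev <- 1 - sum((Xc - A %*% S_raw)^2) / sum(Xc^2)
  S <- t(apply(S_raw, 1L, zscore))
  structure(list(spatial_maps = S, time_courses = A,
                 brain_mask = run$brain_mask, tr_seconds = run$tr_seconds,
                 explained_variance = ev,
                 features = NULL, labels = NULL, truth_tags = NULL),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("component_set: %d components x %d voxels, %.1f%% variance\n",
              nrow(x$spatial_maps), ncol(x$spatial_maps),
              100 * x$explained_variance))
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

#' High/low-frequency power ratio of a component time course
#'
#' Ratio of integrated periodogram power above `split_hz` to power at or
#' below it (mean periodogram, no taper, on the z-scored series).  Components
#' dominated by cardiac or respiratory rhythms score high.  With
#' `as_fraction = TRUE` the high-frequency power fraction
#' (high / total) is returned instead of the ratio.
#'
#' @param tc numeric time series.
#' @param tr_seconds sampling interval, seconds.
#' @param split_hz split frequency (default 0.2 Hz).
#' @param as_fraction return the power fraction rather than the ratio.
#' @return Nonnegative real; `Inf` if the low-frequency power is zero.
#' @export
hf_ratio <- function(tc, tr_seconds, split_hz = 0.2, as_fraction = FALSE) {
  if (split_hz >= nyquist_hz(tr_seconds))
    stop("split_hz must lie below the Nyquist frequency")
  pg <- periodogram(zscore(tc), tr_seconds)
  hi <- sum(pg$power[pg$freq > split_hz])
  lo <- sum(pg$power[pg$freq <= split_hz])
  if (as_fraction) {
    tot <- hi + lo
    return(if (tot == 0) 0 else hi / tot)
  }
  if (lo == 0) return(Inf)
  hi / lo
}

#' Non-gray-matter involvement of a component map
#'
#' The component map is smoothed (Gaussian, `fwhm_mm`), z-scored over the
#' mask and thresholded at `|z| > z_threshold`; the index is one minus the
#' mean of the weighted tissue mask `(gm + wm) / 2` over the suprathreshold
#' voxels (the division by 2 compensates partial-volume dilution at BOLD
#' resolution).  1 means entirely outside gray/white tissue.
#'
#' @param spatial_map 3D array (or in-mask vector with `mask` given).
#' @param tissue a [make_tissue_model()] result.
#' @param fwhm_mm smoothing kernel FWHM (default 8 mm).
#' @param z_threshold threshold on |z| (default 1).
#' @param voxel_size_mm voxel size for the kernel.
#' @param mask logical 3D analysis mask (defaults to any-tissue voxels).
#' @return Real in \[0, 1\]; if no voxel survives the threshold, returns 1
#'   with attribute `empty = TRUE`.
#' @export
nongray_index <- function(spatial_map, tissue, fwhm_mm = 8, z_threshold = 1,
                          voxel_size_mm = c(4, 4, 4), mask = NULL) {
  w <- (tissue$gm_prob + tissue$wm_prob) / 2
  if (is.null(mask))
    mask <- (tissue$gm_prob + tissue$wm_prob + tissue$csf_prob) > 0
  if (is.null(dim(spatial_map)))
    spatial_map <- unmask(spatial_map, mask)
  stopifnot(identical(dim(spatial_map), dim(w)))
  sm <- smooth_gaussian3d(spatial_map, fwhm_mm, voxel_size_mm, mask = mask)
  z <- array(0, dim(sm))
  z[mask] <- zscore(sm[mask])
  sel <- mask & abs(z) > z_threshold
  if (!any(sel)) return(structure(1, empty = TRUE))
  1 - mean(w[sel])
}

#' Slice dependency of a component map
#'
#' Ratio of the mean non-DC spatial Fourier power along the slice (Z) axis
#' to that along the in-plane Y axis.  Components alternating between
#' neighbouring slices (multiband/motion artifacts, respiration-locked
#' motion) score far above 1; spatially isotropic components score near 1.
#'
#' @param spatial_map 3D array (or in-mask vector with `mask`).
#' @param mask optional logical 3D array used to embed a vector map.
#' @return Positive real; `Inf` if the Y-axis power is zero.
#' @export
slice_dependency <- function(spatial_map, mask = NULL) {
  if (is.null(dim(spatial_map))) {
    stopifnot(!is.null(mask))
    spatial_map <- unmask(spatial_map, mask)
  }
  d <- dim(spatial_map)
  if (d[2] < 2 || d[3] < 2) stop("grid needs >= 2 planes along Y and Z")
  axis_power <- function(vol, axis) {
    perm <- if (axis == 2) c(2, 1, 3) else c(3, 1, 2)
    m <- matrix(aperm(vol, perm), nrow = d[axis])
    P <- Mod(stats::mvfft(m))^2
    mean(P[-1, , drop = FALSE])  # exclude DC
  }
  pz <- axis_power(spatial_map, 3)
  py <- axis_power(spatial_map, 2)
  if (py == 0) return(Inf)
  pz / py
}

#' Compute the three noise features for every component
#'
#' @param components a `component_set` from [decompose_ica()].
#' @param tissue a [make_tissue_model()] result.
#' @param split_hz spectral split frequency for [hf_ratio()].
#' @param fwhm_mm,z_threshold spatial-map smoothing/threshold for
#'   [nongray_index()].
#' @param voxel_size_mm voxel size in millimetres.
#' @return The `component_set` with a `features` data frame
#'   (`hf_ratio`, `nongray_index`, `slice_dependency`).
#' @export
compute_features <- function(components, tissue, split_hz = 0.2,
                             fwhm_mm = 8, z_threshold = 1,
                             voxel_size_mm = c(4, 4, 4)) {
  K <- nrow(components$spatial_maps)
  mask <- components$brain_mask
  feats <- data.frame(hf_ratio = numeric(K), nongray_index = numeric(K),
                      slice_dependency = numeric(K))
  for (k in seq_len(K)) {
    m <- components$spatial_maps[k, ]
    feats$hf_ratio[k] <- hf_ratio(components$time_courses[, k],
                                  components$tr_seconds, split_hz)
    feats$nongray_index[k] <- nongray_index(m, tissue, fwhm_mm, z_threshold,
                                            voxel_size_mm, mask = mask)
    feats$slice_dependency[k] <- slice_dependency(m, mask = mask)
  }
  components$features <- feats
  components
}

#' Denoising strength definitions
#'
#' Threshold sets over the three component features, in increasing strength:
#' `slice_only` (slice dependency alone), `Dn1` (spectral only,
#' ratio > 0.6), `Dn2` (adds non-gray > 0.6 and slice > 4), `Dn3`
#' (spectral > 0.4, tissue threshold 0.5, slice > 3).  A component is noise
#' when any active feature exceeds its threshold.
#'
#' @param name one of `"slice_only"`, `"Dn1"`, `"Dn2"`, `"Dn3"`.
#' @param dn3_gray_reading for `Dn3` only.  The Dn3 tissue cutoff is stated
#'   as a mean gray-matter index of 0.5 where the other levels threshold the
#'   NON-gray index; the default (`FALSE`) takes the complementary reading
#'   consistent with Dn1/Dn2 (noise when `nongray_index > 0.5`), while
#'   `TRUE` applies the literal exceeds-the-threshold rule to the gray index
#'   itself (noise when `1 - nongray_index > 0.5`).
#' @return A `denoise_level` list with `hf_threshold`, `nongray_threshold`,
#'   `slice_threshold` (inactive thresholds are `NA`).
#' @export
denoise_level <- function(name = c("Dn2", "Dn1", "Dn3", "slice_only"),
                          dn3_gray_reading = FALSE) {
  name <- match.arg(name)
  lv <- switch(name,
    slice_only = list(hf = NA_real_, nongray = NA_real_, slice = 4),
    Dn1 = list(hf = 0.6, nongray = NA_real_, slice = NA_real_),
    Dn2 = list(hf = 0.6, nongray = 0.6, slice = 4),
    Dn3 = list(hf = 0.4, nongray = 0.5, slice = 3))
  structure(list(name = name, hf_threshold = lv$hf,
                 nongray_threshold = lv$nongray, slice_threshold = lv$slice,
                 dn3_gray_reading = dn3_gray_reading && name == "Dn3"),
            class = "denoise_level")
}

#' Classify components as signal or noise at a denoising strength
#'
#' A component is labeled noise when at least one active feature exceeds its
#' threshold.
#'
#' @param components a `component_set` with computed features.
#' @param level a [denoise_level()] (or its name).
#' @return The `component_set` with `labels` set to `"signal"`/`"noise"`.
#' @export
classify_components <- function(components, level = denoise_level("Dn2")) {
  if (is.character(level)) level <- denoise_level(level)
  f <- components$features
  if (is.null(f)) stop("features not computed; run compute_features() first")
  noise <- rep(FALSE, nrow(f))
  if (!is.na(level$hf_threshold))
    noise <- noise | f$hf_ratio > level$hf_threshold
  if (!is.na(level$nongray_threshold)) {
    if (isTRUE(level$dn3_gray_reading))
      noise <- noise | (1 - f$nongray_index) > level$nongray_threshold
    else
      noise <- noise | f$nongray_index > level$nongray_threshold
  }
  if (!is.na(level$slice_threshold))
    noise <- noise | f$slice_dependency > level$slice_threshold
  components$labels <- ifelse(noise, "noise", "signal")
  components
}

#' Non-aggressive component removal by joint regression
#'
#' Regresses every voxel series on all component time courses jointly and
#' subtracts only the fitted contribution of the target-labeled components,
#' so shared variance between kept and removed components is not removed
#' (non-aggressive cleanup).  `target = "signal"` inverts the operation and
#' yields the noise-only dataset.
#'
#' @param run a [bold_run()].
#' @param components a labeled `component_set`.
#' @param target which label to remove, `"noise"` (default) or `"signal"`.
#' @return Cleaned [bold_run()].
#' @export
remove_components <- function(run, components, target = c("noise", "signal")) {
  target <- match.arg(target)
  if (is.null(components$labels)) stop("components are not labeled")
  rm_idx <- which(components$labels == target)
  if (!length(rm_idx)) return(run)
  X <- run_matrix(run)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  D <- components$time_courses
  D <- sweep(D, 2L, colMeans(D))
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    keep_cols <- qrD$pivot[seq_len(qrD$rank)]
    warning("dropping ", ncol(D) - qrD$rank, " collinear component columns")
    D <- D[, keep_cols, drop = FALSE]
    rm_idx <- which(keep_cols %in% rm_idx)
    if (!length(rm_idx)) return(run)
    qrD <- qr(D)
  }
  B <- qr.coef(qrD, Xc)                    # K x V joint fit
  fitted_rm <- D[, rm_idx, drop = FALSE] %*% B[rm_idx, , drop = FALSE]
  run_from_matrix(sweep(Xc - fitted_rm, 2L, mu, `+`), run,
                  note = paste0("remove_", target))
}

#' Match recovered components to planted ground-truth components
#'
#' Greedy assignment by maximal absolute time-course correlation (each truth
#' component and each recovered component used at most once).
#'
#' @param components a `component_set`.
#' @param truth a `phantom_truth` (its `component_truth` time courses for the
#'   matching run are used).
#' @param run_index which run's truth time courses to use (`NULL` =
#'   concatenate all, matching a concatenated run).
#' @param discard_volumes frames dropped from each truth run before
#'   concatenation (mirror of [normalize_concat()]).
#' @param low_hz,high_hz optional band edges: each truth run segment is
#'   passed through the same zero-phase filter the data saw before the
#'   decomposition, so matching is fair for components the filter attenuates
#'   (drift in particular).
#' @param tr_seconds sampling interval (defaults to the component set's).
#' @return Data frame: truth `name`, `class`, matched `component`, `abs_cor`.
#' @export
match_components <- function(components, truth, run_index = NULL,
                             discard_volumes = 0L, low_hz = NULL,
                             high_hz = NULL,
                             tr_seconds = components$tr_seconds) {
  prep_seg <- function(col) {
    col <- col[(discard_volumes + 1):length(col)]
    if (!is.null(low_hz) || !is.null(high_hz))
      col <- fft_bandpass(col, tr_seconds, low_hz, high_hz)
    zscore(col)
  }
  tc_truth <- lapply(truth$component_truth, function(ct) {
    M <- ct$time_courses
    if (!is.null(run_index)) M <- M[, run_index, drop = FALSE]
    as.vector(apply(M, 2L, prep_seg))
  })
  names(tc_truth) <- vapply(truth$component_truth, `[[`, "", "name")
  A <- components$time_courses
  nT <- nrow(A)
  cors <- sapply(tc_truth, function(y) {
    if (length(y) != nT || stats::sd(y) == 0) return(rep(0, ncol(A)))
    abs(colcor(A, y))
  })                                        # K x n_truth
  cors[is.na(cors)] <- 0
  out <- data.frame(name = names(tc_truth),
                    class = vapply(truth$component_truth, `[[`, "", "class"),
                    component = NA_integer_, abs_cor = NA_real_)
  avail_k <- rep(TRUE, ncol(A))
  avail_t <- rep(TRUE, length(tc_truth))
  for (step in seq_len(min(ncol(A), length(tc_truth)))) {
    sub <- cors
    sub[!avail_k, ] <- -1
    sub[, !avail_t] <- -1
    ij <- arrayInd(which.max(sub), dim(sub))
    if (sub[ij] < 0) break
    out$component[ij[2]] <- ij[1]
    out$abs_cor[ij[2]] <- cors[ij]
    avail_k[ij[1]] <- FALSE
    avail_t[ij[2]] <- FALSE
  }
  out
}
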