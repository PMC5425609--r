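#' Seed-based functional connectivity map
#'
#' Per-voxel Pearson correlation with the mean series over a seed region
#' (e.g. posterior cingulate for the default-mode network, paracingulate for
#' the executive control network).
#'
#' @param run a [bold_run()].
#' @param seed a [roi_mask()] (or logical 3D array).
#' @return An `fc_map`: `values` (3D array of correlations, 0 outside the
#'   brain mask), `valid_mask`, `seed_name`, `seed_mask`.
#' @export
seed_fc <- function(run, seed) {
  name <- if (inherits(seed, "roi_mask")) seed$name else "seed"
  roi <- if (inherits(seed, "roi_mask")) seed$mask else seed
  if (!any(roi)) stop("empty seed ROI")
  X <- run_matrix(run)
  vox <- mask_idx(run$brain_mask)
  cols <- which(vox %in% which(roi))
  if (!length(cols)) stop("seed lies outside the brain mask")
  ref <- rowMeans(X[, cols, drop = FALSE])
  if (stats::sd(ref) == 0) stop("flat seed time course")
  r <- colcor(X, ref)
  valid_in <- !is.na(r)
  r[!valid_in] <- 0
  structure(list(values = unmask(r, run$brain_mask),
                 valid_mask = unmask(valid_in, run$brain_mask, fill = FALSE),
                 seed_name = name, seed_mask = roi),
            class = "fc_map")
}

#' @export
print.fc_map <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf("fc_map [%s]: %d voxels, r in %.2f..%.2f\n",
              x$seed_name, length(v), min(v), max(v)))
  invisible(x)
}

#' White-matter / CSF nuisance regression
#'
#' Regresses the WM-mean and CSF-mean series (plus intercept) out of every
#' in-mask voxel.  Collinear regressors are dropped with a warning.
#'
#' @param run a [bold_run()].
#' @param wm,csf [roi_mask()] objects (or logical arrays).
#' @return Residual [bold_run()] (per-voxel mean retained).
#' @export
nuisance_regress <- function(run, wm, csf) {
  get_mask <- function(m) if (inherits(m, "roi_mask")) m$mask else m
  X <- run_matrix(run)
  vox <- mask_idx(run$brain_mask)
  mean_sig <- function(roi) {
    cols <- which(vox %in% which(get_mask(roi)))
    if (!length(cols)) stop("nuisance ROI outside the brain mask")
    rowMeans(X[, cols, drop = FALSE])
  }
  D <- cbind(wm = mean_sig(wm), csf = mean_sig(csf))
  D <- sweep(D, 2L, colMeans(D))
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("collinear nuisance regressors; dropping ", ncol(D) - qrD$rank)
    D <- D[, qrD$pivot[seq_len(qrD$rank)], drop = FALSE]
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  resid <- Xc - D %*% qr.coef(qr(D), Xc)
  run_from_matrix(sweep(resid, 2L, mu, `+`), run, note = "wmcsf_regress")
}

#' In-network vs out-of-network contrast of an FC map
#'
#' Mean correlation over the network footprint (seed voxels excluded) minus
#' the mean over the remaining in-mask voxels — the scalar summary used to
#' compare denoising conditions.
#'
#' @param fc an `fc_map` from [seed_fc()].
#' @param network logical 3D array of the network's true footprint.
#' @param mask logical 3D analysis mask.
#' @return Numeric contrast.
#' @export
fc_network_contrast <- function(fc, network, mask) {
  sel_in <- network & mask & !fc$seed_mask & fc$valid_mask
  sel_out <- mask & !network & !fc$seed_mask & fc$valid_mask
  mean(fc$values[sel_in]) - mean(fc$values[sel_out])
}
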