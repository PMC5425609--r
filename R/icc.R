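#' Single-measure absolute-agreement intraclass correlation
#'
#' Two-way ANOVA decomposition of a measurements x objects matrix (rows =
#' repeated measurements, e.g. sessions; columns = objects, e.g. voxels or
#' subjects), followed by the McGraw–Wong absolute-agreement single-measure
#' ICC:
#' \deqn{ICC = \frac{MS_{obj} - MS_E}{MS_{obj} + (k-1) MS_E +
#'   \frac{k}{n}(MS_{meas} - MS_E)}}
#' with `k` measurements and `n` objects.  `formula = "printed"` selects a
#' variant in which the measurement (column-term) component enters the
#' denominator with opposite sign,
#' `(MS_obj - MS_E) / (MS_obj + (k-1) MS_E - k/n (MS_meas - MS_E))`,
#' matching a formulation sometimes printed with the subtraction; the two
#' differ whenever the measurement effect is nonzero and both are reported
#' by [print.icc_result()].
#'
#' @param m numeric matrix, rows = measurements (k >= 2), columns = objects
#'   (n >= 2), finite entries.
#' @param formula `"mcgraw_wong"` (default) or `"printed"`.
#' @return An `icc_result`: `value`, mean squares `ms_rows` (measurements),
#'   `ms_cols` (objects), `ms_error`, `n_rows`, `n_cols`, `formula`, and
#'   `value_alt` under the other formula.  A matrix with zero total variance
#'   yields `value = 1` with attribute `degenerate = TRUE`.
#' @export
icc_a1 <- function(m, formula = c("mcgraw_wong", "printed")) {
  formula <- match.arg(formula)
  m <- as.matrix(m)
  k <- nrow(m); n <- ncol(m)
  if (k < 2 || n < 2) stop("need >= 2 measurements and >= 2 objects")
  if (!all(is.finite(m))) stop("non-finite entries")
  ms <- icc_mean_squares(m)
  degenerate <- ms$ss_total < 1e-300
  val <- function(f) {
    if (degenerate) return(1)
    num <- ms$ms_cols - ms$ms_error
    den <- if (f == "mcgraw_wong")
      ms$ms_cols + (k - 1) * ms$ms_error + (k / n) * (ms$ms_rows - ms$ms_error)
    else
      ms$ms_cols + (k - 1) * ms$ms_error - (k / n) * (ms$ms_rows - ms$ms_error)
    if (den == 0) return(1)
    num / den
  }
  out <- structure(
    list(value = val(formula),
         value_alt = val(setdiff(c("mcgraw_wong", "printed"), formula)),
         ms_rows = ms$ms_rows, ms_cols = ms$ms_cols, ms_error = ms$ms_error,
         n_rows = k, n_cols = n, formula = formula),
    class = "icc_result")
  attr(out, "degenerate") <- degenerate
  out
}

# Two-way ANOVA mean squares from row/column/grand means.
icc_mean_squares <- function(m) {
  k <- nrow(m); n <- ncol(m)
  gm <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  ss_rows <- n * sum((rm_ - gm)^2)
  ss_cols <- k * sum((cm - gm)^2)
  ss_total <- sum((m - gm)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  list(ms_rows = ss_rows / (k - 1), ms_cols = ss_cols / (n - 1),
       ms_error = ss_err / ((k - 1) * (n - 1)), ss_total = ss_total)
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) [%s] = %.4f (%s: %.4f); band: %s\n", x$formula,
              x$value, setdiff(c("mcgraw_wong", "printed"), x$formula),
              x$value_alt, icc_band(x$value)))
  cat(sprintf("  MS meas %.4g, MS obj %.4g, MS err %.4g (k=%d, n=%d)\n",
              x$ms_rows, x$ms_cols, x$ms_error, x$n_rows, x$n_cols))
  invisible(x)
}

#' Qualitative reliability band of an ICC value
#'
#' Convention: below 0.2 poor, 0.2–0.39 fair, 0.4–0.59 moderate,
#' 0.6–0.79 good, 0.8 and above excellent.
#'
#' @param value ICC value(s).
#' @return Character vector of band labels.
#' @export
icc_band <- function(value) {
  cut(value, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
      labels = c("poor", "fair", "moderate", "good", "excellent"),
      right = FALSE)
}

#' Whole-image between-session reliability (ICC_between)
#'
#' Arranges two 3D maps as a 2 x V matrix (sessions as rows, in-mask voxels
#' as columns) and computes [icc_a1()].  Seed regions can be excluded via
#' `exclude`.
#'
#' @param map_a,map_b 3D arrays (or `lag_map`/`fc_map` objects, whose joint
#'   valid mask is intersected in).
#' @param mask logical 3D analysis mask (or [roi_mask()]).
#' @param exclude optional logical 3D array (or [roi_mask()]) removed from
#'   the mask (e.g. the FC seed regions).
#' @param formula passed to [icc_a1()].
#' @return An `icc_result`.
#' @export
icc_between <- function(map_a, map_b, mask, exclude = NULL,
                        formula = "mcgraw_wong") {
  getm <- function(m) if (is.list(m)) m$values else m
  getv <- function(m) if (is.list(m)) m$valid_mask else NULL
  sel <- if (inherits(mask, "roi_mask")) mask$mask else mask
  for (v in list(getv(map_a), getv(map_b))) if (!is.null(v)) sel <- sel & v
  if (!is.null(exclude)) {
    ex <- if (inherits(exclude, "roi_mask")) exclude$mask else exclude
    sel <- sel & !ex
  }
  if (!any(sel)) stop("empty mask after exclusion")
  icc_a1(rbind(getm(map_a)[sel], getm(map_b)[sel]), formula = formula)
}

#' Voxelwise reliability map (ICC_within)
#'
#' For every voxel, arranges the values across measurements (rows) and
#' subjects (columns) and computes the absolute-agreement single-measure
#' ICC, yielding a reproducibility map.
#'
#' @param maps either a measurements x subjects list-of-lists of 3D arrays,
#'   or a 4D/matrix arrangement: an array with dim
#'   `c(n_measurements, n_subjects, grid)` is accepted as is.
#' @param mask logical 3D analysis mask.
#' @param formula passed to [icc_a1()].
#' @return List: `values` (3D ICC map), `valid_mask` (voxels where all
#'   entries were finite).
#' @export
icc_within_map <- function(maps, mask, formula = "mcgraw_wong") {
  if (is.list(maps)) {
    k <- length(maps); n <- length(maps[[1]])
    grid <- dim(maps[[1]][[1]])
    arr <- array(NA_real_, c(k, n, prod(grid)))
    for (i in seq_len(k)) for (j in seq_len(n))
      arr[i, j, ] <- as.vector(maps[[i]][[j]])
  } else {
    stopifnot(length(dim(maps)) == 5)
    k <- dim(maps)[1]; n <- dim(maps)[2]
    grid <- dim(maps)[3:5]
    arr <- array(maps, c(k, n, prod(grid)))
  }
  if (k < 2 || n < 2) stop("need >= 2 measurements and >= 2 subjects")
  vox <- which(as.vector(mask))
  vals <- rep(NA_real_, prod(grid))
  ok <- rep(FALSE, prod(grid))
  for (v in vox) {
    m <- arr[, , v]
    if (all(is.finite(m))) {
      vals[v] <- icc_a1(m, formula = formula)$value
      ok[v] <- TRUE
    }
  }
  vals[!ok] <- 0
  list(values = array(vals, grid), valid_mask = array(ok, grid) & mask)
}

#' Image preservation (similarity with a reference map)
#'
#' Realized as the Pearson correlation over in-mask voxels
#' (`method = "pearson"`), or as the whole-image absolute-agreement ICC
#' (`method = "icc"`), between a derived map and its reference (e.g. the
#' map from the undecimated dataset).
#'
#' @param map,reference 3D arrays (or `lag_map`/`fc_map` objects).
#' @param mask logical 3D analysis mask (or [roi_mask()]).
#' @param method `"pearson"` or `"icc"`.
#' @return Numeric similarity; `NA` with a warning if either map is
#'   constant over the mask.
#' @export
image_similarity <- function(map, reference, mask,
                             method = c("pearson", "icc")) {
  method <- match.arg(method)
  getm <- function(m) if (is.list(m)) m$values else m
  getv <- function(m) if (is.list(m)) m$valid_mask else NULL
  sel <- if (inherits(mask, "roi_mask")) mask$mask else mask
  for (v in list(getv(map), getv(reference))) if (!is.null(v)) sel <- sel & v
  a <- getm(map)[sel]; b <- getm(reference)[sel]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant map; similarity undefined")
    return(NA_real_)
  }
  if (method == "pearson") stats::cor(a, b) else icc_a1(rbind(a, b))$value
}

#' Friedman rank test across conditions
#'
#' Nonparametric repeated-measures comparison of conditions (columns) across
#' subjects (rows); wraps the standard rank-based chi-square test, with a
#' degenerate-input guard: if every subject ranks all conditions identically
#' (zero rank variance, e.g. identical columns), the statistic is 0 and
#' p = 1.
#'
#' @param m numeric matrix, subjects x conditions.
#' @return List: `statistic` (chi-square), `p_value`, `df`.
#' @export
friedman_test <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 subjects and conditions")
  ranks <- t(apply(m, 1L, rank))
  if (max(abs(sweep(ranks, 2L, (ncol(m) + 1) / 2))) == 0)
    return(list(statistic = 0, p_value = 1, df = ncol(m) - 1L))
  ft <- stats::friedman.test(m)
  stat <- unname(ft$statistic)
  if (!is.finite(stat))
    return(list(statistic = 0, p_value = 1, df = ncol(m) - 1L))
  list(statistic = stat, p_value = ft$p.value, df = unname(ft$parameter))
}
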