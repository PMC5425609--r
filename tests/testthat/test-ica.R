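# Synthetic run with K planted components on disjoint sparse footprints
# (random-sign patterns on small blocks: spatially near-mean-zero and
# mutually uncorrelated, the regime spatial ICA assumes).
planted_run <- function(K = 5, nt = 240, seed = 20) {
  set.seed(seed)
  d <- c(12, 12, 12)
  mask <- array(TRUE, d)
  nv <- prod(d)
  fp <- matrix(0, K, nv)
  tcs <- matrix(0, nt, K)
  t <- (seq_len(nt) - 1) * 0.5
  # DFT-aligned frequencies: time courses exactly orthogonal over the window
  freqs <- (c(3, 9, 14, 27, 48) / (nt * 0.5))[seq_len(K)]
  vox_pool <- sample(nv)
  for (k in seq_len(K)) {
    block <- vox_pool[(k - 1) * 60 + 1:60]
    fp[k, block] <- sample(c(-1, 1), 60, replace = TRUE)
    tcs[, k] <- sin(2 * pi * freqs[k] * t)
  }
  X <- 100 + tcs %*% fp
  list(run = bold_run(array(t(X), c(d, nt)), 0.5, mask), tcs = tcs, fp = fp)
}

test_that("spatial ICA recovers planted orthogonal-footprint components", {
  pl <- planted_run(K = 5)
  cs <- decompose_ica(pl$run, n_components = 5, seed = 2)
  # every planted time course matches some recovered component
  matched <- integer(0)
  for (k in 1:5) {
    r <- abs(stats::cor(cs$time_courses, pl$tcs[, k]))
    best <- which.max(r)
    expect_gte(max(r), 0.95)
    matched <- c(matched, best)
  }
  expect_equal(sort(unique(matched)), 1:5)
  # mixing reconstructs the data up to the declared residual
  expect_gte(cs$explained_variance, 0.999)
  # K = 1 on rank-1 data
  one <- planted_run(K = 1)
  cs1 <- decompose_ica(one$run, n_components = 1, seed = 2)
  expect_gte(abs(stats::cor(cs1$time_courses[, 1], one$tcs[, 1])), 1 - 1e-6)
  cst <- bold_run(array(7, c(6, 6, 6, 20)), 0.5, array(TRUE, c(6, 6, 6)))
  expect_error(decompose_ica(cst, 3), "degenerate")
})

test_that("high/low-frequency power ratio matches the periodogram oracle", {
  tr <- 0.5
  t <- (0:599) * tr
  lowf <- sin(2 * pi * 0.05 * t)
  expect_lt(hf_ratio(lowf, tr), 1e-3)
  both <- sin(2 * pi * 0.1 * t) + sin(2 * pi * 0.4 * t)
  # equal-amplitude lines either side of the 0.2 Hz split -> ratio ~ 1
  expect_equal(hf_ratio(both, tr), 1, tolerance = 0.05)
  # oracle: direct periodogram integration of the z-scored series
  z <- (both - mean(both)) / stats::sd(both)
  p <- Mod(stats::fft(z))^2
  f <- (seq_along(z) - 1) / (length(z) * tr)
  f <- pmin(f, 1 / tr - f)
  sel <- seq_len(length(z) / 2) + 1
  oracle <- sum(p[sel][f[sel] > 0.2]) / sum(p[sel][f[sel] <= 0.2])
  expect_equal(hf_ratio(both, tr), oracle, tolerance = 1e-10)
  expect_equal(hf_ratio(both, tr, as_fraction = TRUE), oracle / (1 + oracle),
               tolerance = 1e-10)
  highonly <- sin(2 * pi * 0.45 * t)
  expect_gt(hf_ratio(highonly, tr), 1e6)  # effectively no low-band power
  expect_identical(hf_ratio(c(1, -1, 1, -1, 1, -1, 1, -1), tr), Inf)
  expect_error(hf_ratio(lowf, tr, split_hz = 1.5), "Nyquist")
})

test_that("non-gray index reflects the weighted (gm+wm)/2 mask arithmetic", {
  d <- c(12, 12, 12)
  gm <- array(0, d); wm <- array(0, d); csf <- array(0, d)
  gm[4:9, 4:9, 4:9] <- 1
  csf[1:2, , ] <- 1
  tis <- structure(list(gm_prob = gm, wm_prob = wm, csf_prob = csf),
                   class = "tissue_model")
  mask <- array(TRUE, d)
  inside <- array(0, d); inside[5:8, 5:8, 5:8] <- 10
  # confined to gm=1, wm=0 voxels: index = 1 - 1/2
  expect_equal(nongray_index(inside, tis, fwhm_mm = 0, voxel_size_mm = c(4, 4, 4),
                             mask = mask), 0.5)
  outside <- array(0, d); outside[1:2, 5:8, 5:8] <- 10
  expect_equal(nongray_index(outside, tis, fwhm_mm = 0, mask = mask), 1)
  # mixed-tissue map equals a direct masked-mean recomputation
  set.seed(23)
  wm2 <- array(stats::runif(prod(d)) * 0.5, d)
  tis2 <- structure(list(gm_prob = gm, wm_prob = wm2, csf_prob = csf * 0),
                    class = "tissue_model")
  m <- array(stats::rnorm(prod(d)), d)
  got <- nongray_index(m, tis2, fwhm_mm = 8, z_threshold = 1,
                       voxel_size_mm = c(4, 4, 4), mask = mask)
  sm <- smooth_gaussian3d(m, 8, c(4, 4, 4), mask = mask)
  z <- (sm - mean(sm)) / stats::sd(sm)
  sel <- abs(z) > 1
  expect_equal(got, 1 - mean(((gm + wm2) / 2)[sel]), tolerance = 1e-12)
  # nothing suprathreshold -> 1 with flag
  flat <- array(0, d)
  res <- nongray_index(flat, tis, fwhm_mm = 0, mask = mask)
  expect_equal(as.numeric(res), 1)
  expect_true(isTRUE(attr(res, "empty")))
})

test_that("slice dependency separates slice-alternating from isotropic maps", {
  d <- c(12, 12, 12)
  set.seed(24)
  ratios <- replicate(20, slice_dependency(array(stats::rnorm(prod(d)), d)))
  expect_equal(mean(ratios), 1, tolerance = 0.15)
  alt <- array(0, d)
  for (z in seq_len(d[3])) alt[, , z] <- (-1)^z
  r_alt <- slice_dependency(alt)
  expect_identical(r_alt, Inf)  # constant in Y: zero in-plane power
  altn <- alt + array(stats::rnorm(prod(d), sd = 0.05), d)
  r2 <- slice_dependency(altn)
  expect_gt(r2, 4)
  # oracle: direct FFT power along each axis
  pz <- mean(apply(altn, c(1, 2), function(l) mean(Mod(stats::fft(l))[-1]^2)))
  py <- mean(apply(altn, c(1, 3), function(l) mean(Mod(stats::fft(l))[-1]^2)))
  expect_equal(r2, pz / py, tolerance = 1e-10)
  expect_error(slice_dependency(array(1, c(5, 1, 5))), "planes")
})

test_that("classification applies the graded threshold sets and is monotone", {
  fake <- function(hf, ng, sl) {
    structure(list(spatial_maps = matrix(0, length(hf), 10),
                   time_courses = matrix(0, 50, length(hf)),
                   features = data.frame(hf_ratio = hf, nongray_index = ng,
                                         slice_dependency = sl)),
              class = "component_set")
  }
  cs <- fake(hf = c(0.7, 0.5, 0), ng = c(0.1, 0.7, 0), sl = c(1, 1, 0))
  expect_equal(classify_components(cs, "Dn1")$labels,
               c("noise", "signal", "signal"))
  expect_equal(classify_components(cs, "Dn2")$labels,
               c("noise", "noise", "signal"))
  expect_equal(classify_components(fake(0, 0, 5), "slice_only")$labels, "noise")
  # Dn3 default vs gray-index reading of the tissue cutoff
  amb <- fake(0, 0.55, 1)
  expect_equal(classify_components(amb, denoise_level("Dn3"))$labels, "noise")
  expect_equal(classify_components(
    amb, denoise_level("Dn3", dn3_gray_reading = TRUE))$labels, "signal")
  # monotone: every Dn1 noise component is Dn3 noise (hf 0.4 < 0.6)
  set.seed(25)
  rnd <- fake(stats::runif(200, 0, 1.2), stats::runif(200),
              stats::runif(200, 0, 6))
  n1 <- classify_components(rnd, "Dn1")$labels == "noise"
  n3 <- classify_components(rnd, "Dn3")$labels == "noise"
  expect_true(all(n3[n1]))
  nofeat <- fake(1, 1, 1)
  nofeat$features <- NULL
  expect_error(classify_components(nofeat, "Dn1"), "features")
})

test_that("non-aggressive removal subtracts only the fitted noise contribution", {
  pl <- planted_run(K = 4, nt = 300)
  # a perfect decomposition: the planted time courses themselves
  cs <- structure(list(spatial_maps = pl$fp, time_courses = pl$tcs,
                       brain_mask = pl$run$brain_mask, tr_seconds = 0.5,
                       labels = rep("signal", 4)),
                  class = "component_set")
  # no noise labeled: identity
  same <- remove_components(pl$run, cs, target = "noise")
  expect_equal(same$data, pl$run$data, tolerance = 1e-12)
  # remove the 0.4 Hz source: residual correlation with it vanishes
  # (projection oracle), and no voxel gains variance
  cs$labels <- c("signal", "signal", "signal", "noise")
  cleaned <- remove_components(pl$run, cs, target = "noise")
  Xc <- series_matrix(cleaned)
  resid_cor <- suppressWarnings(abs(stats::cor(Xc, pl$tcs[, 4])))
  expect_lt(max(resid_cor, na.rm = TRUE), 1e-6)
  v0 <- apply(series_matrix(pl$run), 2, stats::var)
  v1 <- apply(Xc, 2, stats::var)
  expect_true(all(v1 <= v0 + 1e-8))
  # the same removal through an estimated decomposition is a projection up
  # to the ICA tolerance
  est <- decompose_ica(pl$run, n_components = 4, seed = 3)
  est$labels <-
    ifelse(seq_len(4) == which.max(abs(stats::cor(est$time_courses,
                                                  pl$tcs[, 4]))),
           "noise", "signal")
  Xe <- series_matrix(remove_components(pl$run, est, target = "noise"))
  expect_lt(max(suppressWarnings(abs(stats::cor(Xe, pl$tcs[, 4]))),
                na.rm = TRUE), 0.05)
  ve <- apply(Xe, 2, stats::var)
  expect_true(all(ve <= v0 * (1 + 1e-6) + 1e-8))
})
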