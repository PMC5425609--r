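test_that("cross-correlogram honours the positive-upstream polarity contract", {
  set.seed(30)
  ref <- as.numeric(stats::filter(rnorm(400), rep(1, 8), sides = 2))
  ref[is.na(ref)] <- 0
  expect_equal(unname(lagged_correlogram(ref, ref, 0L)), 1)
  # series leading the reference by 3 frames peaks at +3 (full search)
  lead3 <- c(ref[4:400], rep(0, 3))
  cg <- lagged_correlogram(lead3, ref, -6:6)
  expect_equal(as.integer(names(which.max(cg))), 3L)
  # the -4..+6 s grid at TR 0.5 has 21 shift values
  expect_equal(length(seq(round(-4 / 0.5), round(6 / 0.5))), 21L)
  # short overlap is marked invalid
  expect_true(is.na(lagged_correlogram(ref, ref, 395L)))
  # two-voxel toy: A = reference advanced by 1 s -> lag +1 s (A upstream)
  tr <- 0.5
  A <- c(ref[3:400], 0, 0)  # leads by 2 frames = 1 s
  cgA <- lagged_correlogram(A, ref, -8:8)
  expect_equal(as.integer(names(which.max(cgA))) * tr, 1)
})

test_that("Lag-SSS recovers a noise-free planted field exactly on the TR grid", {
  ph <- clean_phantom(1200)
  run <- temporal_filter(ph$runs[[1]], 0.008, 0.16)
  m <- lag_sss(run, ph$truth$rois$sss_seed, fwhm_mm = 0)
  st <- lag_truth_stats(m, ph$truth$lag_field)
  expect_gte(st$frac_exact, 0.99)
  # ROI voxels sit at lag ~ 0 by construction
  expect_lt(max(abs(m$values[ph$truth$rois$sss_seed$mask])), 0.5 + 1e-9)
  # smoothing is a mask-renormalized Gaussian of the unsmoothed map
  ms <- lag_sss(run, ph$truth$rois$sss_seed, fwhm_mm = 8,
                voxel_size_mm = c(4, 4, 4))
  expect_equal(ms$values,
               smooth_gaussian3d(m$values, 8, c(4, 4, 4), mask = m$valid_mask),
               tolerance = 1e-12)
  expect_error(lag_sss(run, array(FALSE, dim(run$brain_mask))), "empty")
})

test_that("Lag-rec tracks a planted field and collapses on a flat one", {
  ph <- noisy_phantom()
  run <- temporal_filter(ph$runs[[1]], 0.008, 0.16)
  rec <- lag_rec(run)
  st <- lag_truth_stats(rec$map, ph$truth$lag_field, align = "median")
  expect_gte(st$frac_within_tr, 0.95)
  expect_true(all(diff(rec$seed_traces$lag_seconds) > 0))
  expect_true(all(rec$seed_traces$n_voxels >= 1))
  # flat field: everything assigned at lag 0, no outward seeds
  flat_cfg <- phantom_config(n_timepoints = 400, n_runs = 1, noise_sd = 0,
                             cardiac_amplitude = 0, resp_amplitude = 0,
                             drift_amplitude = 0, neural_amplitude = 0,
                             lag_range_s = c(0, 0), rng_seed = 41L)
  flat <- make_phantom(flat_cfg)
  fr <- lag_rec(temporal_filter(flat$runs[[1]], 0.008, 0.16))
  expect_true(all(fr$map$values[fr$map$valid_mask] == 0))
  expect_equal(nrow(fr$seed_traces), 1L)
})

test_that("dispersion-mode phantoms show seed-trace amplitude decay with lag", {
  cfg <- phantom_config(n_timepoints = 1000, n_runs = 1, noise_sd = 0.1,
                        cardiac_amplitude = 0, resp_amplitude = 0,
                        drift_amplitude = 0, neural_amplitude = 0,
                        lag_range_s = c(-2, 4), lag_style = "tree",
                        dispersion = TRUE, upstream_decay = 0.5,
                        rng_seed = 43L)
  ph <- make_phantom(cfg)
  rec <- lag_rec(temporal_filter(ph$runs[[1]], 0.008, 0.16))
  st <- rec$seed_traces
  mid <- st$amplitude[st$lag_seconds == 0]
  hi <- st$amplitude[which.max(st$lag_seconds)]
  expect_lt(hi, mid)
  # amplitudes on the upstream branch drop by more than a third overall
  up <- st$amplitude[st$lag_seconds >= 0]
  expect_lt(up[length(up)] / up[1], 2 / 3)
})

test_that("Lag-SSS and Lag-rec agree within one TR on noiseless pure-translation phantoms", {
  # 13 in-mask planes over -2..4 s put one plane on each TR step
  cfg <- phantom_config(grid_shape = c(15, 16, 16), n_timepoints = 1000,
                        n_runs = 1, noise_sd = 0, cardiac_amplitude = 0,
                        resp_amplitude = 0, drift_amplitude = 0,
                        neural_amplitude = 0, lag_range_s = c(-2, 4),
                        lag_style = "gradient", rng_seed = 47L)
  ph <- make_phantom(cfg)
  run <- temporal_filter(ph$runs[[1]], 0.008, 0.16)
  msss <- lag_sss(run, ph$truth$rois$sss_seed, fwhm_mm = 0)
  rec <- lag_rec(run)
  cmp <- compare_lag_maps(msss, rec$map)
  # maps agree up to the constant reference offset, within one TR
  ctr <- cmp$difference - stats::median(cmp$difference)
  expect_lte(max(abs(ctr)), run$tr_seconds + 1e-9)
  expect_gte(mean(ctr == 0), 0.95)
})

test_that("Laplace hole filling is exact on harmonic inputs and bounded by its boundary", {
  d <- c(16, 16, 16)
  co <- arrayInd(seq_len(prod(d)), d)
  ramp <- array(1 + 0.2 * co[, 1] - 0.1 * co[, 2] + 0.05 * co[, 3], d)
  valid <- array(TRUE, d)
  m0 <- lag_map(ramp, valid, "rec", 0.5, c(-4, 4))
  expect_identical(fill_holes(m0)$values, ramp)  # no holes: identity
  # single hole surrounded by a constant
  cst <- array(3, d)
  v1 <- valid; v1[8, 8, 8] <- FALSE
  f1 <- fill_holes(lag_map(ifelse(v1, cst, 0), v1, "rec", 0.5, c(-4, 4)))
  expect_equal(f1$values[8, 8, 8], 3, tolerance = 1e-9)
  # random hole patterns on an affine ramp: exact to 1e-3, maximum principle
  set.seed(31)
  for (i in 1:5) {
    holes <- random_holes(d, 350)
    v <- valid; v[holes] <- FALSE
    f <- fill_holes(lag_map(ifelse(v, ramp, 0), v, "rec", 0.5, c(-4, 4)))
    expect_lt(max(abs(f$values[holes] - ramp[holes])), 1e-3)
    expect_true(all(f$values[holes] <= max(ramp[v]) + 1e-9))
    expect_true(all(f$values[holes] >= min(ramp[v]) - 1e-9))
    expect_identical(f$values[v], ramp[v])  # valid voxels untouched
  }
  none <- lag_map(ramp, array(FALSE, d), "rec", 0.5, c(-4, 4))
  expect_error(fill_holes(none), "valid")
})

test_that("lag map comparison statistics behave on degenerate and shifted maps", {
  ph <- clean_phantom(1200)
  run <- temporal_filter(ph$runs[[1]], 0.008, 0.16)
  m <- lag_sss(run, ph$truth$rois$sss_seed, fwhm_mm = 0)
  self <- compare_lag_maps(m, m)
  expect_equal(self$correlation, 1)
  expect_true(all(self$difference == 0))
  shifted <- m
  shifted$values <- m$values + 1
  cs <- compare_lag_maps(shifted, m)
  expect_equal(cs$correlation, 1)
  expect_true(all(cs$difference == 1))
  expect_equal(sum(cs$histogram$counts > 0), 1L)  # point mass at +1
})

test_that("shuffling time points destroys lag recovery", {
  ph <- noisy_phantom()
  run <- temporal_filter(ph$runs[[1]], 0.008, 0.16)
  st0 <- lag_truth_stats(lag_sss(run, ph$truth$rois$sss_seed, fwhm_mm = 0),
                         ph$truth$lag_field, align = "median")
  set.seed(33)
  perm <- sample(dim(run$data)[4])
  run_p <- bold_run(run$data[, , , perm], run$tr_seconds, run$brain_mask)
  m <- lag_sss(run_p, ph$truth$rois$sss_seed, fwhm_mm = 0)
  st <- lag_truth_stats(m, ph$truth$lag_field, align = "median")
  # temporal order carries the lag information: permutation wipes the
  # voxelwise agreement, leaving at most the weak ordinal residue that
  # shift-zero correlations (which survive a common permutation) induce
  expect_gte(st0$frac_within_tr, 0.95)
  expect_lt(st$frac_within_tr, 0.5)
  expect_lt(abs(st$correlation), 0.5)
})
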