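test_that("gradient lag field spans the requested range with the sinus at its minimum", {
  cfg <- phantom_config(rng_seed = 3L, snap_lag_tr = FALSE)
  lf <- make_lag_field(cfg, style = "gradient", range_s = c(-4, 6))
  mask <- attr(lf, "mask")
  expect_equal(range(lf[mask]), c(-4, 6))
  # monotone along the flow axis
  expect_true(all(diff(lf[2:15, 8, 8]) > 0))
  g <- boldlag:::phantom_geometry(cfg$grid_shape)
  expect_equal(min(lf[g$sss]), min(lf[mask]))
  expect_error(make_lag_field(cfg, style = "spiral"), "style")
})

test_that("tree lag field declares the positive fraction it actually has", {
  cfg <- phantom_config(rng_seed = 7L, lag_style = "tree",
                        lag_range_s = c(-1, 5))
  lf <- make_lag_field(cfg)
  mask <- attr(lf, "mask")
  expect_equal(attr(lf, "positive_fraction"), mean(lf[mask] > 0))
  expect_gt(attr(lf, "positive_fraction"), 0.5)
  expect_true(all(lf[mask] >= -1 - 1e-9 & lf[mask] <= 5 + 1e-9))
  g <- boldlag:::phantom_geometry(cfg$grid_shape)
  expect_equal(min(lf[g$sss]), min(lf[mask]))
})

test_that("sLFO series is band-limited, deterministic, and silent at zero amplitude", {
  cfg <- phantom_config()
  s <- make_slfo(cfg, n_seconds = 600, dt = 0.5, seed = 5L)
  pg_frac <- local({
    n <- length(s)
    p <- Mod(stats::fft(s))^2
    f <- (seq_len(n) - 1) / (n * 0.5)
    f <- pmin(f, 2 - f)
    sum(p[f >= 0.01 & f <= 0.1]) / sum(p[-1])
  })
  expect_gte(pg_frac, 0.95)
  expect_equal(mean(s), 0, tolerance = 1e-10)
  expect_identical(s, make_slfo(cfg, 600, dt = 0.5, seed = 5L))
  cfg0 <- phantom_config(slfo_amplitude = 0)
  expect_identical(make_slfo(cfg0, 60, dt = 0.5), numeric(120))
  bad <- phantom_config()
  bad$slfo_band_hz <- c(0.01, 3)
  expect_error(make_slfo(bad, 60, dt = 0.5), "Nyquist")
})

test_that("phantom generation is deterministic and conserves a flat noise-free field", {
  cfg <- phantom_config(n_timepoints = 80, n_runs = 2, noise_sd = 0,
                        cardiac_amplitude = 0, resp_amplitude = 0,
                        drift_amplitude = 0, neural_amplitude = 0,
                        lag_range_s = c(0, 0), rng_seed = 21L)
  p1 <- make_phantom(cfg)
  p2 <- make_phantom(cfg)
  expect_identical(p1$runs[[1]]$data, p2$runs[[1]]$data)
  expect_identical(p1$truth$lag_field, p2$truth$lag_field)
  # flat lag field, no structured noise: every in-mask voxel = global mean
  X <- series_matrix(p1$runs[[1]])
  gm <- rowMeans(X)
  expect_lt(max(abs(X - gm)), 1e-9)
})

test_that("noise-free translation phantom obeys the full-search shift oracle", {
  ph <- clean_phantom(600)
  run <- ph$runs[[1]]
  X <- series_matrix(run)
  lag_in <- ph$truth$lag_field[run$brain_mask]
  set.seed(8)
  pick <- sample(ncol(X), 12)
  for (i in 1:6) {
    a <- pick[2 * i - 1]; b <- pick[2 * i]
    true_d <- round((lag_in[a] - lag_in[b]) / run$tr_seconds)
    # voxel a leads voxel b by true_d frames
    expect_equal(full_search_shift(X[, a], X[, b], 14), true_d)
  }
})

test_that("breath-hold response shows an early peak before the delayed maximum", {
  cfg <- phantom_config(n_timepoints = 360, n_runs = 1, noise_sd = 0.1,
                        rng_seed = 31L)
  ev <- event_list(onsets = 40, durations = 10, kinds = "breath_hold")
  ph <- make_phantom(cfg, events = ev)
  gmean <- rowMeans(series_matrix(ph$runs[[1]]))
  tt <- (seq_along(gmean) - 1) * 0.5 - 40
  base <- mean(gmean[tt < 0 & tt > -10])
  resp <- gmean - base
  in_early <- tt >= 3 & tt <= 7
  after <- tt >= 3 & tt <= 40
  t_peak_abs <- tt[after][which.max(resp[after])]
  expect_gt(t_peak_abs, 7)  # absolute maximum is the delayed vasodilatory peak
  early <- resp[in_early]
  # local maximum inside 3..7 s window
  imax <- which.max(early)
  expect_true(imax > 1 && imax < length(early))
})

test_that("event generators respect the stated timing designs", {
  ev <- make_events("srt", run_length_s = 300, seed = 2L)
  iti <- diff(ev$onset)
  expect_true(all(iti >= 6 & iti <= 24))
  bh <- make_events("breath_hold", run_length_s = 540)
  expect_true(all(bh$duration == 10))
  expect_true(all(diff(bh$onset) == 100))  # 10 s hold + 90 s rest
  expect_error(event_list(c(5, 5)), "increasing")
  cfg <- phantom_config(n_timepoints = 40, n_runs = 1)
  expect_error(make_phantom(cfg, events = event_list(100)), "duration")
})

test_that("cardiac aliasing arithmetic lands at Nyquist then folds to DC", {
  expect_equal(alias_frequency(1.0, fs_hz = 2), 1.0)   # Nyquist of TR 0.5
  expect_equal(alias_frequency(1.0, fs_hz = 1), 0.0)   # TR 1.0: folds to DC
  expect_equal(alias_frequency(0.97, fs_hz = 1), 0.03, tolerance = 1e-12)
  expect_equal(alias_frequency(0.97, fs_hz = 2 / 3), abs(0.97 - 2 / 3),
               tolerance = 1e-12)
})
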