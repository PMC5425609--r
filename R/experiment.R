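#' Build the graded denoising datasets of a session
#'
#' Runs are high-pass filtered (0.008 Hz), transition frames discarded, each
#' voxel normalized and runs concatenated; the concatenated session is
#' decomposed by spatial ICA, the three noise features computed and the
#' requested denoising strengths applied by non-aggressive regression.  The
#' `"raw"` dataset skips removal; `"noise_only"` removes the
#' signal-labeled components of the Dn3 classification instead, leaving the
#' noise subspace.  All datasets are finally band-pass filtered
#' (0.008–0.16 Hz), the common preparation for lag and connectivity mapping.
#'
#' @param runs list of [bold_run()] (one session).
#' @param tissue a [make_tissue_model()] result.
#' @param levels character vector from `"raw"`, `"slice_only"`, `"Dn1"`,
#'   `"Dn2"`, `"Dn3"`, `"noise_only"`.
#' @param n_components ICA dimensionality.
#' @param discard_volumes initial frames dropped per run.
#' @param band_hz final band-pass edges.
#' @param highpass_hz pre-ICA high-pass edge.
#' @param voxel_size_mm voxel size (feature smoothing kernel).
#' @param seed RNG seed for the ICA rotation.
#' @return List: `datasets` (named list of [bold_run()]), `components`
#'   (the featured `component_set`), `labels` (per level), `concat` (the
#'   band-passed raw concatenation).
#' @export
denoise_datasets <- function(runs, tissue,
                             levels = c("raw", "slice_only", "Dn1", "Dn2",
                                        "Dn3", "noise_only"),
                             n_components = 12L, discard_volumes = 20L,
                             band_hz = c(0.008, 0.16), highpass_hz = 0.008,
                             voxel_size_mm = c(4, 4, 4), seed = 1L) {
  hp <- lapply(runs, temporal_filter, low_hz = highpass_hz, high_hz = NULL)
  concat <- normalize_concat(hp, discard_volumes)
  comps <- decompose_ica(concat, n_components = n_components, seed = seed)
  comps <- compute_features(comps, tissue, voxel_size_mm = voxel_size_mm)
  bp <- function(r) temporal_filter(r, band_hz[1], band_hz[2])
  datasets <- list()
  labels <- list()
  for (lv in levels) {
    if (lv == "raw") {
      datasets[[lv]] <- bp(concat)
    } else if (lv == "noise_only") {
      cl <- classify_components(comps, denoise_level("Dn3"))
      labels[[lv]] <- cl$labels
      datasets[[lv]] <- bp(remove_components(concat, cl, target = "signal"))
    } else {
      cl <- classify_components(comps, denoise_level(lv))
      labels[[lv]] <- cl$labels
      datasets[[lv]] <- bp(remove_components(concat, cl, target = "noise"))
    }
  }
  list(datasets = datasets, components = comps, labels = labels,
       concat = bp(concat))
}

#' Run the full phantom reliability experiment
#'
#' Simulates two sessions of the same phantom subject (shared structural
#' truth — lag field, footprints — with independent session noise), builds
#' the graded denoising datasets for each, derives the four standard maps
#' per dataset (Lag-SSS, hole-filled Lag-rec, and seed FC for the DMN-like
#' and ECN-like networks), and reports between-session reliability
#' (ICC_between, FC seeds masked out for the FC metrics) together with
#' phantom-truth recovery diagnostics for the lag maps.
#'
#' @param config a [phantom_config()].
#' @param levels denoising strengths (see [denoise_datasets()]).
#' @param n_components ICA dimensionality.
#' @param seed master seed: sessions use `seed + 1` and `seed + 2`.
#' @param events optional [event_list()] per run.
#' @param shift_range_s Lag-SSS search range.
#' @param lag_fwhm_mm Lag-SSS map smoothing.
#' @return List: `report` (data frame dataset x metric with `icc_between`,
#'   `band`, `similarity_between`), `lag_truth` (data frame of truth-recovery
#'   statistics per dataset and session), `maps`, `truth`.
#' @export
run_experiment <- function(config = phantom_config(),
                           levels = c("raw", "slice_only", "Dn1", "Dn2",
                                      "Dn3", "noise_only"),
                           n_components = 12L, seed = 1L, events = NULL,
                           shift_range_s = c(-4, 6), lag_fwhm_mm = 8) {
  sessions <- lapply(1:2, function(s)
    make_phantom(config, events = events, session_seed = seed + s))
  truth <- sessions[[1]]$truth
  rois <- truth$rois
  g <- phantom_geometry(config$grid_shape)
  mask <- sessions[[1]]$runs[[1]]$brain_mask
  vs <- config$voxel_size_mm

  maps <- list()
  for (s in 1:2) {
    dn <- denoise_datasets(sessions[[s]]$runs, truth$tissue, levels = levels,
                           n_components = n_components, voxel_size_mm = vs,
                           seed = seed + 10 * s)
    maps[[s]] <- lapply(dn$datasets, function(ds) {
      rec <- lag_rec(ds)
      list(lag_sss = lag_sss(ds, rois$sss_seed, shift_range_s,
                             fwhm_mm = lag_fwhm_mm, voxel_size_mm = vs),
           lag_rec = fill_holes(rec$map, mask = mask),
           fc_dmn = seed_fc(ds, rois$pcc_seed),
           fc_ecn = seed_fc(ds, rois$ecn_seed))
    })
  }

  metric_names <- c("lag_sss", "lag_rec", "fc_dmn", "fc_ecn")
  seed_excl <- rois$pcc_seed$mask | rois$ecn_seed$mask
  rows <- list()
  for (ds in names(maps[[1]])) {
    for (mt in metric_names) {
      a <- maps[[1]][[ds]][[mt]]
      b <- maps[[2]][[ds]][[mt]]
      excl <- if (startsWith(mt, "fc")) seed_excl else NULL
      icc <- icc_between(a, b, mask, exclude = excl)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds, metric = mt, icc_between = icc$value,
        band = as.character(icc_band(icc$value)),
        similarity_between = image_similarity(a, b, mask))
    }
  }
  report <- do.call(rbind, rows)

  lt <- list()
  for (s in 1:2) for (ds in names(maps[[s]])) {
    st_sss <- lag_truth_stats(maps[[s]][[ds]]$lag_sss, truth$lag_field,
                              mask = mask)
    st_rec <- lag_truth_stats(maps[[s]][[ds]]$lag_rec, truth$lag_field,
                              mask = mask, align = "median")
    lt[[length(lt) + 1L]] <- data.frame(
      session = s, dataset = ds,
      sss_truth_cor = st_sss$correlation, sss_within_tr = st_sss$frac_within_tr,
      rec_truth_cor = st_rec$correlation, rec_within_tr = st_rec$frac_within_tr)
  }
  list(report = report, lag_truth = do.call(rbind, lt), maps = maps,
       truth = truth)
}

#' Sampling-rate (decimation) sweep
#'
#' Decimates a prepared dataset by the given factors without anti-alias
#' filtering (the raw series is deliberately not high-pass filtered before
#' decimation), band-pass filters each decimated dataset (the upper edge is
#' clipped just below the new Nyquist frequency where necessary), recomputes
#' the Lag-SSS and DMN FC maps, and measures image preservation against the
#' factor-1 maps.  The apparent cardiac frequency after folding is reported
#' per factor.
#'
#' @param runs list of raw [bold_run()] (no temporal filtering applied).
#' @param rois phantom ROI set (needs `sss_seed`, `pcc_seed`).
#' @param cardiac_hz the cardiac frequency carried by the data.
#' @param factors integer decimation factors (default 1:10).
#' @param discard_volumes initial frames dropped per run.
#' @param band_hz nominal band-pass.
#' @param shift_range_s,lag_fwhm_mm,voxel_size_mm lag-mapping parameters.
#' @return Data frame per factor: effective TR, aliased cardiac frequency,
#'   `sim_lag_sss` and `sim_fc_dmn` image preservation.
#' @export
decimation_sweep <- function(runs, rois, cardiac_hz = 1.0, factors = 1:10,
                             discard_volumes = 20L, band_hz = c(0.008, 0.16),
                             shift_range_s = c(-4, 6), lag_fwhm_mm = 8,
                             voxel_size_mm = c(4, 4, 4)) {
  concat <- normalize_concat(runs, discard_volumes)
  mask <- concat$brain_mask
  ref_maps <- NULL
  rows <- list()
  for (f in sort(unique(c(1L, factors)))) {
    dec <- decimate_run(concat, f)
    nyq <- nyquist_hz(dec$tr_seconds)
    hi <- min(band_hz[2], 0.999 * nyq)
    ds <- temporal_filter(dec, band_hz[1], hi)
    m_lag <- lag_sss(ds, rois$sss_seed, shift_range_s, fwhm_mm = lag_fwhm_mm,
                     voxel_size_mm = voxel_size_mm)
    m_fc <- seed_fc(ds, rois$pcc_seed)
    if (f == 1L) ref_maps <- list(lag = m_lag, fc = m_fc)
    rows[[length(rows) + 1L]] <- data.frame(
      factor = f, tr_effective = dec$tr_seconds,
      cardiac_alias_hz = alias_frequency(cardiac_hz, 1 / dec$tr_seconds),
      band_hi_hz = hi,
      sim_lag_sss = image_similarity(m_lag, ref_maps$lag, mask),
      sim_fc_dmn = image_similarity(m_fc, ref_maps$fc, mask))
  }
  out <- do.call(rbind, rows)
  out[out$factor %in% factors, , drop = FALSE]
}
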