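#' Configuration for a synthetic BOLD phantom
#'
#' Bundles the geometry, sampling and signal-model parameters of the
#' synthetic 4D BOLD generator.  Signals are generated on a fine temporal
#' grid (`tr_seconds / oversample`) before sampling at the repetition time,
#' so supra-Nyquist physiological content (the ~1 Hz cardiac rhythm at
#' TR = 0.5 s) exists in the continuous model and can alias under
#' decimation.
#'
#' All amplitudes are on a percent-signal-change-like scale relative to a
#' baseline of 100.
#'
#' @param grid_shape three positive integers, voxels per axis.
#' @param voxel_size_mm voxel dimensions in millimetres.
#' @param tr_seconds repetition time, seconds.
#' @param n_timepoints frames per run.
#' @param n_runs number of runs.
#' @param rng_seed integer seed controlling structural randomness (tree-style
#'   lag fields) and, by default, the session noise.
#' @param slfo_band_hz two reals, the systemic low-frequency oscillation band.
#' @param slfo_amplitude sLFO amplitude (standard deviation at the most
#'   downstream voxel).
#' @param cardiac_hz,cardiac_amplitude cardiac rhythm frequency and amplitude
#'   (vessel/CSF-adjacent footprint, first harmonic included).
#' @param resp_hz,resp_amplitude respiratory rhythm frequency and amplitude
#'   (slice-alternating footprint).
#' @param noise_sd white-noise standard deviation.
#' @param drift_amplitude low-order scanner drift amplitude (non-gray,
#'   edge-of-brain footprint).
#' @param neural_amplitude amplitude of network fluctuations and task
#'   responses in gray matter.
#' @param bh_amplitude amplitude of the breath-hold global vasodilatory
#'   response.
#' @param hrf_peak_s,hrf_undershoot_s double-gamma hemodynamic response
#'   peak and undershoot times, seconds.
#' @param lag_range_s declared range of the planted lag field, seconds
#'   (positive = upstream / earlier arrival).
#' @param lag_style `"gradient"` or `"tree"`.
#' @param upstream_decay fractional sLFO amplitude loss from the most
#'   downstream to the most upstream voxel (0 = flat amplitude map).
#' @param dispersion logical; progressively low-pass the sLFO waveform with
#'   distance upstream, emulating waveform dispersion along the vascular
#'   tree.
#' @param snap_lag_tr snap planted lags to the TR grid (the lag-map contract
#'   is TR-discrete).
#' @param oversample fine-grid factor for the continuous signal model.
#' @return An object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(grid_shape = c(16, 16, 16),
                           voxel_size_mm = c(4, 4, 4),
                           tr_seconds = 0.5,
                           n_timepoints = 624,
                           n_runs = 2,
                           rng_seed = 1L,
                           slfo_band_hz = c(0.01, 0.1),
                           slfo_amplitude = 1,
                           cardiac_hz = 1.0,
                           cardiac_amplitude = 0.6,
                           resp_hz = 0.25,
                           resp_amplitude = 0.6,
                           noise_sd = 0.25,
                           drift_amplitude = 1,
                           neural_amplitude = 0.8,
                           bh_amplitude = 2,
                           hrf_peak_s = 6,
                           hrf_undershoot_s = 16,
                           lag_range_s = c(0, 6),
                           lag_style = "gradient",
                           upstream_decay = 0.4,
                           dispersion = FALSE,
                           snap_lag_tr = TRUE,
                           oversample = 20L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = as.numeric(voxel_size_mm),
              tr_seconds = tr_seconds, n_timepoints = as.integer(n_timepoints),
              n_runs = as.integer(n_runs), rng_seed = as.integer(rng_seed),
              slfo_band_hz = slfo_band_hz, slfo_amplitude = slfo_amplitude,
              cardiac_hz = cardiac_hz, cardiac_amplitude = cardiac_amplitude,
              resp_hz = resp_hz, resp_amplitude = resp_amplitude,
              noise_sd = noise_sd, drift_amplitude = drift_amplitude,
              neural_amplitude = neural_amplitude, bh_amplitude = bh_amplitude,
              hrf_peak_s = hrf_peak_s, hrf_undershoot_s = hrf_undershoot_s,
              lag_range_s = lag_range_s, lag_style = lag_style,
              upstream_decay = upstream_decay, dispersion = dispersion,
              snap_lag_tr = snap_lag_tr, oversample = as.integer(oversample))
  validate_phantom_config(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (length(grid_shape) != 3 || any(grid_shape < 8))
      stop("grid_shape must be 3 integers >= 8")
    if (tr_seconds <= 0 || n_timepoints < 2 || n_runs < 1)
      stop("invalid sampling parameters")
    if (slfo_band_hz[1] <= 0 || slfo_band_hz[2] <= slfo_band_hz[1])
      stop("slfo_band_hz must be an increasing positive pair")
    if (slfo_band_hz[2] >= nyquist_hz(tr_seconds))
      stop("sLFO band upper edge must lie below the Nyquist frequency")
    fine_nyq <- oversample / (2 * tr_seconds)
    if (cardiac_hz >= fine_nyq)
      stop("cardiac_hz not representable on the fine grid; raise oversample")
    amps <- c(slfo_amplitude, cardiac_amplitude, resp_amplitude, noise_sd,
              drift_amplitude, neural_amplitude, bh_amplitude)
    if (any(amps < 0)) stop("amplitudes must be nonnegative")
    if (!lag_style %in% c("gradient", "tree"))
      stop("unknown lag field style: ", lag_style)
  })
  invisible(cfg)
}

# ---- geometry ---------------------------------------------------------------

# Abstract phantom anatomy: a box brain mask; a midline "vessel" column along
# x (the flow axis) standing in for the sagittal sinus and large vessels; a
# CSF-like outer shell; a white-matter core; gray matter elsewhere, holding
# two two-block "networks" (DMN-like and ECN-like).
phantom_geometry <- function(grid_shape) {
  d <- grid_shape
  ax <- function(i) 2:(d[i] - 1)
  mask <- array(FALSE, d)
  mask[ax(1), ax(2), ax(3)] <- TRUE

  c2 <- function(i) floor(d[i] / 2) + 0:1
  vessel <- array(FALSE, d)
  vessel[ax(1), c2(2), c2(3)] <- TRUE

  shell <- array(FALSE, d)
  shell[mask] <- TRUE
  inner <- array(FALSE, d)
  inner[3:(d[1] - 2), 3:(d[2] - 2), 3:(d[3] - 2)] <- TRUE
  shell <- shell & !inner

  core_band <- function(i) max(3, round(0.3 * d[i])):min(d[i] - 2, round(0.72 * d[i]))
  wm <- array(FALSE, d)
  wm[core_band(1), core_band(2), core_band(3)] <- TRUE
  wm <- wm & !vessel & !shell

  lo <- function(i) max(3, round(0.25 * d[i])):max(4, round(0.4 * d[i]))
  hi <- function(i) min(d[i] - 3, round(0.62 * d[i])):min(d[i] - 3, round(0.8 * d[i]))
  xn <- (d[1] - 4):(d[1] - 3)   # downstream gray matter, clear of the shell
  xf <- 4:5                     # upstream gray matter
  blk <- function(xs, ys, zs) {
    b <- array(FALSE, d); b[xs, ys, zs] <- TRUE; b & mask & !vessel & !wm
  }
  pcc   <- blk(xn, lo(2), lo(3))
  dmn2  <- blk(xf, lo(2), hi(3))
  ecn   <- blk(xn, hi(2), hi(3))
  ecn2  <- blk(xf, hi(2), lo(3))
  motor <- blk(xf, hi(2), hi(3))   # designated task-response region

  sss <- array(FALSE, d)
  sss[2:3, c2(2), c2(3)] <- TRUE

  csf <- (vessel | shell) & mask
  gm <- mask & !csf & !wm

  list(mask = mask, vessel = vessel, shell = shell, wm = wm, gm = gm,
       csf = csf, sss = sss, pcc = pcc, dmn2 = dmn2, ecn = ecn, ecn2 = ecn2,
       motor = motor, dmn_network = pcc | dmn2, ecn_network = ecn | ecn2)
}

#' Tissue probability model of the phantom
#'
#' Crisp-but-probabilistic gray matter, white matter and CSF probability
#' maps over the abstract phantom anatomy (each in \[0, 1\], summing to at
#' most 1 per voxel).
#'
#' @param grid_shape three positive integers.
#' @return A `tissue_model` list with `gm_prob`, `wm_prob`, `csf_prob`.
#' @export
make_tissue_model <- function(grid_shape) {
  g <- phantom_geometry(grid_shape)
  gm <- wm <- csf <- array(0, grid_shape)
  gm[g$gm] <- 0.9;  wm[g$gm] <- 0.1
  wm[g$wm] <- 0.9;  gm[g$wm] <- 0.1
  csf[g$csf] <- 0.9; gm[g$csf] <- 0.05; wm[g$csf] <- 0.05
  structure(list(gm_prob = gm, wm_prob = wm, csf_prob = csf),
            class = "tissue_model")
}

#' Region-of-interest mask
#'
#' @param mask logical 3D array with at least one voxel set.
#' @param name label for the region.
#' @return A `roi_mask` object.
#' @export
roi_mask <- function(mask, name) {
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("ROI '", name, "' is empty")
  structure(list(mask = mask, name = name), class = "roi_mask")
}

phantom_rois <- function(grid_shape) {
  g <- phantom_geometry(grid_shape)
  tis <- make_tissue_model(grid_shape)
  list(sss_seed = roi_mask(g$sss, "sss_seed"),
       pcc_seed = roi_mask(g$pcc, "pcc_seed"),
       ecn_seed = roi_mask(g$ecn, "ecn_seed"),
       wm = roi_mask(tis$wm_prob > 0.5, "wm"),
       csf = roi_mask(tis$csf_prob > 0.5, "csf"))
}

# ---- lag field --------------------------------------------------------------

#' Plant a voxelwise blood-arrival lag field
#'
#' Positive lags mark upstream voxels (earlier arrival of the circulating
#' sLFO); the sinus seed region holds the field minimum (most downstream).
#' `"gradient"` is a monotone ramp along the flow (x) axis spanning `range_s`;
#' `"tree"` derives lags from graph distance to the sinus seed through the
#' brain mask, with smooth random perturbation.
#'
#' @param config a [phantom_config()].
#' @param style `"gradient"` or `"tree"` (defaults to `config$lag_style`).
#' @param range_s two reals; defaults to `config$lag_range_s`.
#' @return 3D array of seconds (0 outside the brain mask) with attributes
#'   `positive_fraction` (declared fraction of in-mask voxels with positive
#'   lag) and `mask`.
#' @export
make_lag_field <- function(config, style = config$lag_style,
                           range_s = config$lag_range_s) {
  if (!style %in% c("gradient", "tree"))
    stop("unknown lag field style: ", style)
  d <- config$grid_shape
  g <- phantom_geometry(d)
  lag <- array(0, d)
  if (style == "gradient") {
    xs <- 2:(d[1] - 1)
    ramp <- seq(range_s[1], range_s[2], length.out = length(xs))
    for (i in seq_along(xs)) lag[xs[i], , ] <- ramp[i]
  } else {
    dist <- bfs_distance(g$mask, g$sss)
    dmax <- max(dist[g$mask])
    base <- range_s[1] + (range_s[2] - range_s[1]) * (dist / dmax)^0.9
    set.seed(config$rng_seed + 211L)
    pert <- smooth_gaussian3d(array(stats::rnorm(prod(d)), d), fwhm_mm = 10,
                              voxel_size_mm = config$voxel_size_mm,
                              mask = g$mask)
    pert <- pert / max(stats::sd(pert[g$mask]), 1e-12)
    base <- base + 0.06 * (range_s[2] - range_s[1]) * pert * (dist / dmax)
    base <- pmin(pmax(base, range_s[1]), range_s[2])
    base[g$sss] <- range_s[1]
    lag[g$mask] <- base[g$mask]
  }
  if (config$snap_lag_tr)
    lag <- round(lag / config$tr_seconds) * config$tr_seconds
  lag[!g$mask] <- 0
  attr(lag, "positive_fraction") <- mean(lag[g$mask] > 0)
  attr(lag, "mask") <- g$mask
  lag
}

# 6-connected breadth-first graph distance (in voxels) to a source region.
# Neighbours are generated in coordinate space, so there is no wrap-around
# across array edges.
bfs_distance <- function(mask, source) {
  d <- dim(mask)
  dist <- array(Inf, d)
  frontier <- which(source & mask)
  dist[frontier] <- 0
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  step <- 0
  while (length(frontier)) {
    step <- step + 1
    fc <- arrayInd(frontier, d)
    cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
      sweep(fc, 2, offs[k, ], `+`)))
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
          cand[, 2] >= 1 & cand[, 2] <= d[2] &
          cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    idx <- unique(cand[, 1] + (cand[, 2] - 1) * d[1] +
                    (cand[, 3] - 1) * d[1] * d[2])
    idx <- idx[mask[idx] & !is.finite(dist[idx])]
    if (!length(idx)) break
    dist[idx] <- step
    frontier <- idx
  }
  dist[!mask] <- 0
  dist
}

# ---- temporal ingredients ---------------------------------------------------

#' Band-limited systemic low-frequency oscillation
#'
#' Zero-mean Gaussian noise restricted to `config$slfo_band_hz` by Fourier
#' masking, normalized to unit standard deviation (then scaled by
#' `config$slfo_amplitude`).  At least 95% of periodogram power falls inside
#' the band by construction.
#'
#' @param config a [phantom_config()].
#' @param n_seconds series duration, seconds.
#' @param dt sampling interval (defaults to the fine-grid interval).
#' @param seed RNG seed (defaults to `config$rng_seed`).
#' @return Numeric series of length `round(n_seconds / dt)`.
#' @export
make_slfo <- function(config, n_seconds,
                      dt = config$tr_seconds / config$oversample,
                      seed = config$rng_seed) {
  band <- config$slfo_band_hz
  if (band[2] >= 1 / (2 * dt))
    stop("sLFO band exceeds the Nyquist frequency of the requested grid")
  n <- round(n_seconds / dt)
  if (config$slfo_amplitude == 0) return(numeric(n))
  set.seed(seed)
  x <- stats::rnorm(n)
  f <- stats::fft(x)
  freq <- (seq_len(n) - 1) / (n * dt)
  freq <- pmin(freq, 1 / dt - freq)  # fold to physical frequency
  keep <- freq >= band[1] & freq <= band[2]
  keep[1] <- FALSE
  f[!keep] <- 0
  y <- Re(stats::fft(f, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y <- y / s
  y * config$slfo_amplitude
}

# Double-gamma hemodynamic response, unit peak height.
hrf_double_gamma <- function(t, peak_s = 6, undershoot_s = 16,
                             undershoot_ratio = 1 / 6) {
  a1 <- peak_s; a2 <- undershoot_s
  h <- stats::dgamma(t, shape = a1, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = a2, rate = 1)
  h[t < 0] <- 0
  m <- max(h)
  if (m > 0) h <- h / m
  h
}

# Breath-hold global response: a small neurovascular peak near 5 s followed
# by a larger, delayed vasodilatory peak (CO2 reactivity), unit max height.
breath_hold_response <- function(t) {
  early <- 0.35 * hrf_double_gamma(t, peak_s = 5, undershoot_s = 14,
                                   undershoot_ratio = 0)
  late <- stats::dgamma(t - 8, shape = 5, rate = 0.7)
  late[t < 8] <- 0
  if (max(late) > 0) late <- late / max(late)
  r <- early + late
  r / max(r)
}

#' Event timing list
#'
#' Generates task event timings: `"srt"` draws inter-trial intervals
#' uniformly in \[6, 24\] s (a sparse simple-reaction-time design);
#' `"breath_hold"` places 10 s holds separated by 90 s rest.
#'
#' @param kind `"srt"` or `"breath_hold"`.
#' @param run_length_s run duration in seconds.
#' @param seed RNG seed (srt only).
#' @param start_s time of the first onset opportunity.
#' @return An `event_list` data frame with columns onset, duration, kind.
#' @export
make_events <- function(kind = c("srt", "breath_hold"), run_length_s,
                        seed = 1L, start_s = 12) {
  kind <- match.arg(kind)
  if (kind == "srt") {
    set.seed(seed)
    onsets <- numeric(0)
    t <- start_s
    while (t < run_length_s - 20) {
      onsets <- c(onsets, t)
      t <- t + stats::runif(1, 6, 24)
    }
    event_list(onsets, 0.5, "srt")
  } else {
    onsets <- if (start_s + 28 > run_length_s - 40) numeric(0)
              else seq(start_s + 28, run_length_s - 40, by = 100)
    event_list(onsets, 10, "breath_hold")
  }
}

#' @rdname make_events
#' @param onsets strictly increasing onset times, seconds.
#' @param durations event durations, seconds (nonnegative).
#' @param kinds event kind labels.
#' @export
event_list <- function(onsets, durations = 0, kinds = "srt") {
  if (length(onsets) && any(diff(onsets) <= 0))
    stop("onsets must be strictly increasing")
  if (any(durations < 0)) stop("durations must be >= 0")
  ev <- data.frame(onset = as.numeric(onsets),
                   duration = rep_len(as.numeric(durations), length(onsets)),
                   kind = rep_len(as.character(kinds), length(onsets)))
  class(ev) <- c("event_list", "data.frame")
  ev
}

# ---- phantom assembly -------------------------------------------------------

#' Generate a multi-run BOLD phantom with known ground truth
#'
#' Each in-mask voxel's series is assembled as
#' baseline + sLFO shifted by the voxel's planted lag (pure translation, or
#' progressive dispersion) times an amplitude map decaying upstream,
#' plus gray-matter network fluctuations and HRF-convolved task responses,
#' a cardiac sinusoid (with first harmonic) on a vessel/CSF footprint, a
#' respiratory oscillation on a slice-alternating footprint, low-order
#' drift on a brain-edge footprint, white noise, and — for breath-hold
#' events — a global response with a small early peak near 5 s preceding a
#' larger delayed vasodilatory peak.  Everything planted is recorded in the
#' returned truth object.
#'
#' @param config a [phantom_config()].
#' @param events `NULL`, a single [event_list()] applied to every run, or a
#'   list of one event list per run.
#' @param session_seed seed for the session's stochastic content (waveforms,
#'   phases, noise); the structural truth (lag field, footprints) depends
#'   only on `config`.  Two calls with the same config and different
#'   `session_seed` emulate two sessions of the same subject.
#' @return List with `runs` (list of [bold_run()]) and `truth`
#'   (`phantom_truth`: `lag_field`, `component_truth`, `event_onsets`,
#'   `tissue`, `rois`, `amplitude_map`, `config`).
#' @export
make_phantom <- function(config, events = NULL,
                         session_seed = config$rng_seed) {
  d <- config$grid_shape
  g <- phantom_geometry(d)
  tis <- make_tissue_model(d)
  rois <- phantom_rois(d)
  lag <- make_lag_field(config)
  mask <- g$mask
  vox <- mask_idx(mask)
  nv <- length(vox)
  tr <- config$tr_seconds
  nt <- config$n_timepoints
  run_T <- nt * tr
  dt <- tr / config$oversample

  if (!is.null(events) && !inherits(events, "event_list") && !is.list(events))
    stop("events must be NULL, an event_list, or a list of event_lists")
  ev_by_run <- lapply(seq_len(config$n_runs), function(r) {
    ev <- if (is.null(events)) NULL
          else if (inherits(events, "event_list")) events
          else events[[min(r, length(events))]]
    if (!is.null(ev) && nrow(ev) && max(ev$onset) >= run_T)
      stop("event onsets exceed the run duration")
    ev
  })

  # sLFO amplitude map: decays toward upstream voxels.
  lag_in <- lag[vox]
  span <- diff(range(lag_in))
  rel <- if (span > 0) (lag_in - min(lag_in)) / span else rep(0, nv)
  amp_map_in <- 1 - config$upstream_decay * rel
  amp_map <- unmask(amp_map_in, mask)

  frame_t <- (seq_len(nt) - 1) * tr
  pad <- max(abs(config$lag_range_s)) + 4
  fine_t <- seq(-pad, run_T + pad, by = dt)
  uniq_lag <- sort(unique(lag_in))

  set.seed(session_seed)
  run_seeds <- sample.int(2^30, config$n_runs * 8)
  runs <- vector("list", config$n_runs)
  comp_tc <- list(slfo = NULL, dmn = NULL, ecn = NULL, task = NULL,
                  cardiac = NULL, respiratory = NULL, drift = NULL,
                  breath_hold = NULL)

  for (r in seq_len(config$n_runs)) {
    sd_base <- run_seeds[(r - 1) * 8 + 1:8]
    X <- matrix(100, nt, nv)

    # systemic LFO propagated through the lag field (positive lag = leads)
    slfo_fine <- make_slfo(config, n_seconds = diff(range(fine_t)) + dt,
                           dt = dt, seed = sd_base[1])
    slfo_fine <- slfo_fine[seq_along(fine_t)]
    slfo_at <- function(times) {
      stats::approx(fine_t, slfo_fine, xout = times, rule = 2)$y
    }
    slfo_ref <- slfo_at(frame_t)
    if (config$slfo_amplitude > 0) {
      for (L in uniq_lag) {
        src <- slfo_fine
        if (config$dispersion && L > min(uniq_lag)) {
          # dispersion: moving-average low-pass widening with distance upstream
          w_s <- 1.5 * (L - min(uniq_lag))
          wn <- max(1L, round(w_s / dt))
          if (wn > 1)
            src <- as.numeric(stats::filter(src, rep(1 / wn, wn), sides = 2))
        }
        series <- stats::approx(fine_t, src, xout = frame_t + L, rule = 2)$y
        series[is.na(series)] <- 0
        sel <- which(lag_in == L)
        X[, sel] <- X[, sel] + outer(series, amp_map_in[sel])
      }
    }

    # gray-matter network fluctuations (independent band-limited series)
    net_cfg <- config; net_cfg$slfo_amplitude <- 1
    dmn_tc <- make_slfo(net_cfg, run_T, dt = tr, seed = sd_base[2]) *
      config$neural_amplitude
    ecn_tc <- make_slfo(net_cfg, run_T, dt = tr, seed = sd_base[3]) *
      config$neural_amplitude
    dmn_tc <- dmn_tc[seq_len(nt)]; ecn_tc <- ecn_tc[seq_len(nt)]
    in_dmn <- g$dmn_network[vox]; in_ecn <- g$ecn_network[vox]
    if (config$neural_amplitude > 0) {
      X[, in_dmn] <- X[, in_dmn] + dmn_tc
      X[, in_ecn] <- X[, in_ecn] + ecn_tc
    }

    # task responses
    ev <- ev_by_run[[r]]
    task_tc <- numeric(nt); bh_tc <- numeric(nt)
    if (!is.null(ev) && nrow(ev)) {
      srt <- ev[ev$kind == "srt", , drop = FALSE]
      if (nrow(srt)) {
        stick <- numeric(length(fine_t))
        for (i in seq_len(nrow(srt))) {
          on <- srt$onset[i]; du <- max(srt$duration[i], dt)
          stick[fine_t >= on & fine_t < on + du] <- 1
        }
        h <- hrf_double_gamma(seq(0, 32, by = dt), config$hrf_peak_s,
                              config$hrf_undershoot_s)
        resp <- stats::convolve(stick, rev(h), type = "open")[seq_along(fine_t)]
        if (max(abs(resp)) > 0) resp <- resp / max(abs(resp))
        task_tc <- stats::approx(fine_t, resp, xout = frame_t, rule = 2)$y *
          config$neural_amplitude
        in_task <- g$motor[vox]
        X[, in_task] <- X[, in_task] + task_tc
      }
      bh <- ev[ev$kind == "breath_hold", , drop = FALSE]
      if (nrow(bh) && config$bh_amplitude > 0) {
        for (i in seq_len(nrow(bh))) {
          tt <- frame_t - bh$onset[i]
          win <- tt >= 0 & tt <= 40
          bh_tc[win] <- bh_tc[win] + breath_hold_response(tt[win])
        }
        bh_tc <- bh_tc * config$bh_amplitude
        X <- X + matrix(bh_tc, nt, nv)
      }
    }

    # cardiac rhythm on a vessel/CSF-adjacent footprint (fine grid, so
    # supra-Nyquist content is present before sampling)
    set.seed(sd_base[4])
    ph <- stats::runif(2, 0, 2 * pi)
    card_fp_in <- tis$csf_prob[vox]
    card_fine <- sin(2 * pi * config$cardiac_hz * fine_t + ph[1]) +
      0.3 * sin(2 * pi * 2 * config$cardiac_hz * fine_t + ph[2])
    card_tc <- stats::approx(fine_t, card_fine, xout = frame_t)$y *
      config$cardiac_amplitude
    if (config$cardiac_amplitude > 0)
      X <- X + outer(card_tc, card_fp_in)

    # respiratory oscillation, slice-alternating footprint along z
    set.seed(sd_base[5])
    phr <- stats::runif(1, 0, 2 * pi)
    zcoord <- arrayInd(vox, d)[, 3]
    resp_fp_in <- 0.8 * (-1)^zcoord
    resp_fine <- sin(2 * pi * config$resp_hz * fine_t + phr) *
      (1 + 0.3 * sin(2 * pi * 0.03 * fine_t))
    resp_tc <- stats::approx(fine_t, resp_fine, xout = frame_t)$y *
      config$resp_amplitude
    if (config$resp_amplitude > 0)
      X <- X + outer(resp_tc, resp_fp_in)

    # low-order scanner drift on the brain-edge (non-gray) footprint
    set.seed(sd_base[6])
    cf <- stats::rnorm(2)
    u <- frame_t / run_T
    drift_tc <- (cf[1] * (u - 0.5) + cf[2] * (u - 0.5)^2)
    drift_tc <- drift_tc / max(stats::sd(drift_tc), 1e-12) *
      config$drift_amplitude
    drift_fp_in <- as.numeric(g$shell[vox])
    if (config$drift_amplitude > 0)
      X <- X + outer(drift_tc, drift_fp_in)

    # white noise
    if (config$noise_sd > 0) {
      set.seed(sd_base[7])
      X <- X + matrix(stats::rnorm(nt * nv, sd = config$noise_sd), nt, nv)
    }

    arr <- array(0, c(d, nt))
    flat <- matrix(arr, prod(d), nt)
    flat[vox, ] <- t(X)
    arr <- array(flat, c(d, nt))
    runs[[r]] <- bold_run(arr, tr, mask,
                          meta = list(subject = "phantom", session = 1L,
                                      run = r, history = "simulated"))
    add_tc <- function(slot, tc) {
      comp_tc[[slot]] <<- cbind(comp_tc[[slot]], tc)
    }
    add_tc("slfo", slfo_ref); add_tc("dmn", dmn_tc); add_tc("ecn", ecn_tc)
    add_tc("task", task_tc); add_tc("cardiac", card_tc)
    add_tc("respiratory", resp_tc); add_tc("drift", drift_tc)
    add_tc("breath_hold", bh_tc)
  }

  fp3 <- function(v_in) unmask(v_in, mask)
  component_truth <- list(
    list(name = "slfo", class = "slfo", footprint = amp_map,
         time_courses = comp_tc$slfo),
    list(name = "dmn_network", class = "neuronal",
         footprint = fp3(as.numeric(g$dmn_network[vox])),
         time_courses = comp_tc$dmn),
    list(name = "ecn_network", class = "neuronal",
         footprint = fp3(as.numeric(g$ecn_network[vox])),
         time_courses = comp_tc$ecn),
    list(name = "task", class = "neuronal",
         footprint = fp3(as.numeric(g$motor[vox])),
         time_courses = comp_tc$task),
    list(name = "cardiac", class = "cardiac",
         footprint = fp3(tis$csf_prob[vox]),
         time_courses = comp_tc$cardiac),
    list(name = "respiratory", class = "respiratory",
         footprint = fp3(0.8 * (-1)^arrayInd(vox, d)[, 3]),
         time_courses = comp_tc$respiratory),
    list(name = "drift", class = "drift",
         footprint = fp3(as.numeric(g$shell[vox])),
         time_courses = comp_tc$drift),
    list(name = "breath_hold", class = "slfo",
         footprint = unmask(rep(1, nv), mask),
         time_courses = comp_tc$breath_hold))

  truth <- structure(
    list(lag_field = lag, component_truth = component_truth,
         event_onsets = lapply(ev_by_run, function(e) e$onset %||% numeric(0)),
         tissue = tis, rois = rois, amplitude_map = amp_map,
         config = config, session_seed = session_seed),
    class = "phantom_truth")
  list(runs = runs, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("phantom_truth:", paste(dim(x$lag_field), collapse = "x"),
      "grid;", length(x$component_truth), "planted components; lag range",
      paste(round(range(x$lag_field[attr(x$lag_field, "mask")]), 2),
            collapse = ".."), "s\n")
  invisible(x)
}
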