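# Shared fixture builders.  Phantoms are generated in code (no stored data)
# and cached per session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Noise-free pure-translation phantom: sLFO only, gradient lag field.
clean_phantom <- function(n_timepoints = 1200) {
  cached(paste0("clean", n_timepoints), function() {
    cfg <- phantom_config(n_timepoints = n_timepoints, n_runs = 1,
                          noise_sd = 0, cardiac_amplitude = 0,
                          resp_amplitude = 0, drift_amplitude = 0,
                          neural_amplitude = 0, rng_seed = 11L)
    make_phantom(cfg)
  })
}

# Moderate-noise phantom (sLFO-to-noise amplitude ratio 4) on a tree-style
# lag field inside +/-4 s so both mapping methods can track it.
noisy_phantom <- function() {
  cached("noisy", function() {
    cfg <- phantom_config(n_timepoints = 1200, n_runs = 1, noise_sd = 0.25,
                          slfo_amplitude = 1, cardiac_amplitude = 0.4,
                          resp_amplitude = 0.4, drift_amplitude = 0.5,
                          neural_amplitude = 0.5, lag_range_s = c(-2, 4),
                          lag_style = "tree", rng_seed = 13L)
    make_phantom(cfg)
  })
}

# A full rest phantom with every ingredient, two runs, for ICA work.
rest_phantom <- function() {
  cached("rest", function() {
    cfg <- phantom_config(n_timepoints = 624, n_runs = 2, noise_sd = 0.3,
                          cardiac_hz = 0.97, rng_seed = 17L)
    list(phantom = make_phantom(cfg), config = cfg)
  })
}

phantom_mask <- function(ph) ph$runs[[1]]$brain_mask

# In-mask T x V matrix of a run (public-route reimplementation kept tiny so
# tests do not depend on package internals).
series_matrix <- function(run) {
  d <- dim(run$data)
  t(matrix(run$data, prod(d[1:3]), d[4])[which(run$brain_mask), , drop = FALSE])
}

# Independent full-search cross-correlation oracle: best integer shift of y
# relative to x by direct cor() calls.
full_search_shift <- function(x, y, max_shift) {
  shifts <- -max_shift:max_shift
  r <- vapply(shifts, function(s) {
    n <- length(x)
    if (s >= 0) stats::cor(x[seq_len(n - s)], y[(1 + s):n])
    else stats::cor(x[(1 - s):n], y[seq_len(n + s)])
  }, 0)
  shifts[which.max(r)]
}

# Random hole pattern over voxels that keep at least one full axis-neighbour
# pair (the interior; matches the isolated-voxel character of real holes).
random_holes <- function(dims, n, mask = NULL) {
  co <- arrayInd(seq_len(prod(dims)), dims)
  corner <- (co[, 1] %in% c(1, dims[1])) & (co[, 2] %in% c(1, dims[2])) &
    (co[, 3] %in% c(1, dims[3]))
  pool <- which(!corner)
  if (!is.null(mask)) pool <- intersect(pool, which(mask))
  sample(pool, n)
}
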