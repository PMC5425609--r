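#!/usr/bin/env Rscript
# Simulate the phantom datasets used throughout the analysis and write them
# to results/phantom/ as NIfTI + TSV + JSON.  Two sessions of the same
# "subject" share the structural truth (lag field, tissue, footprints) and
# differ only in their session noise, mirroring a test-retest design.

suppressPackageStartupMessages(library(boldlag))
seed <- 1L
out <- "results/phantom"

cfg <- phantom_config(n_timepoints = 624, n_runs = 2, noise_sd = 0.3,
                      cardiac_hz = 0.97, rng_seed = seed)
events <- make_events("srt", run_length_s = 312, seed = seed)

for (ses in 1:2) {
  ph <- make_phantom(cfg, events = events, session_seed = seed + ses)
  write_phantom(ph, file.path(out, sprintf("ses-%d", ses)), events = events)
  message("session ", ses, ": ", length(ph$runs), " runs, lag range ",
          paste(range(ph$truth$lag_field[ph$runs[[1]]$brain_mask]),
                collapse = ".."), " s")
}
message("phantoms written under ", out)
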