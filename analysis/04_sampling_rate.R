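#!/usr/bin/env Rscript
# Sampling-rate experiment: decimate the raw session by factors 1..10
# (effective TR 0.5..5 s) with no anti-alias filtering and measure image
# preservation of the lag and FC maps against the TR 0.5 s originals.
# The near-1 Hz cardiac rhythm folds to a different apparent frequency at
# every factor; where it lands inside the sLFO band the lag map degrades.

suppressPackageStartupMessages(library(boldlag))
seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- phantom_config(n_timepoints = 624, n_runs = 2, noise_sd = 0.2,
                      cardiac_hz = 0.97, cardiac_amplitude = 2,
                      rng_seed = seed)
ph <- make_phantom(cfg, session_seed = seed)
sw <- decimation_sweep(ph$runs, ph$truth$rois, cardiac_hz = cfg$cardiac_hz,
                       factors = 1:10)
write.table(sw, "results/decimation_sweep.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(round(sw, 3), row.names = FALSE)
message("\nNote the preservation notch at factor 2 (TR 1 s), where the ",
        "cardiac alias lands at ", round(sw$cardiac_alias_hz[2], 3),
        " Hz, inside the 0.008-0.16 Hz analysis band.")
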