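#!/usr/bin/env Rscript
# ICA decomposition, the three noise features, and the graded denoising
# datasets for session 1; writes the per-component feature table and the
# per-level classification summary.

suppressPackageStartupMessages(library(boldlag))
seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- phantom_config(n_timepoints = 624, n_runs = 2, noise_sd = 0.3,
                      cardiac_hz = 0.97, rng_seed = seed)
ph <- make_phantom(cfg, session_seed = seed + 1L)
dn <- denoise_datasets(ph$runs, ph$truth$tissue, n_components = 15L,
                       seed = seed)

feats <- dn$components$features
feats$component <- seq_len(nrow(feats))
mm <- match_components(dn$components, ph$truth, discard_volumes = 20L,
                       low_hz = 0.008)
feats$truth_match <- NA_character_
feats$truth_match[mm$component] <- mm$name
write.table(feats, "results/component_features.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

summ <- do.call(rbind, lapply(names(dn$labels), function(lv) {
  data.frame(level = lv,
             n_noise = sum(dn$labels[[lv]] == "noise"),
             pct_noise = 100 * mean(dn$labels[[lv]] == "noise"))
}))
write.table(summ, "results/denoise_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(summ, row.names = FALSE)
message("noise fraction rises with denoising strength; ",
        "features per component in results/component_features.tsv")
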