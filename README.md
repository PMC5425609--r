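# boldlag

Blood circulates, and it carries a marker: a systemic low-frequency
oscillation (sLFO, ~0.01–0.1 Hz) visible in the BOLD fMRI signal wherever
blood flows.  Because the oscillation travels with the blood, its arrival
time varies across the brain by seconds.  Cross-correlating every voxel
against a reference time course turns a resting-state run into a **lag
map** — a voxelwise picture of relative blood transit, with positive lags
marking upstream (earlier-arriving) territory and the draining veins at the
downstream end.

`boldlag` is for researchers who work with these maps and need to know how
they interact with the rest of the fMRI toolchain: ICA-based denoising,
seed-based functional connectivity, sampling rate, and task paradigms.  It
provides:

* **Two lag estimators.** *Lag-SSS*: per voxel, the shift maximizing the
  Pearson correlation with a superior-sagittal-sinus seed over a discrete
  −4…+6 s grid at TR steps.  *Lag-rec*: recursive tracking from the
  global-signal seed in ±TR steps (correlogram local peak ≥ 0.2), with
  Laplace (Dirichlet) interpolation of unassigned holes.
* **ICA denoising with a three-feature noise heuristic** — high/low
  spectral power ratio, non-gray-matter involvement via the (GM+WM)/2
  weighted mask, and slice dependency (Z/Y spatial spectral power) — at
  graded strengths Dn1/Dn2/Dn3, with non-aggressive regression removal and
  the complementary noise-only dataset.
* **Reliability statistics.** Absolute-agreement single-measure ICC,
  ICC(A,1) = (MS_obj − MS_E) / (MS_obj + (k−1)MS_E + k/n·(MS_meas − MS_E)),
  in whole-image (sessions × voxels) and voxelwise (measurements ×
  subjects) arrangements, image preservation, and the Friedman test.
* **Sampling-rate (aliasing) experiments.** Decimation without anti-alias
  filtering plus the folding arithmetic `alias_frequency()`: a ~1 Hz
  cardiac rhythm lands at Nyquist at TR 0.5 s and folds into the sLFO band
  at TR 1 s.
* **Event-locked averaging** for sparse reaction-time tasks and breath
  holds, with isolated-event selection (≥ 9 s before, ≥ 15 s after).
* **A synthetic 4D phantom** (`make_phantom()`) with fully known ground
  truth — planted lag field, component footprints and time courses, event
  responses — so every stage above is testable end to end.  No download is
  needed; all data are generated in code.

The repository is an analysis workflow: computation lives in the package,
and the numbered scripts under `analysis/` (simulate → denoise →
reliability → sampling rate → event averaging) are thin drivers that write
their tables under `results/`.

## Worked example

```r
library(boldlag)

cfg <- phantom_config(n_timepoints = 600, n_runs = 1, noise_sd = 0.25,
                      rng_seed = 42)
ph  <- make_phantom(cfg)                       # runs + ground truth
run <- temporal_filter(ph$runs[[1]], 0.008, 0.16)

m <- lag_sss(run, ph$truth$rois$sss_seed, fwhm_mm = 0)
m
#> lag_map [sss]: 2744 valid voxels, range -0.5..6 s (grid 0.5 s);
#>   positive = upstream / earlier arrival

lag_truth_stats(m, ph$truth$lag_field)
#> truth correlation 0.991; 100.0% of voxels within one TR

rec <- lag_rec(run)
compare_lag_maps(m, rec$map)$correlation
#> [1] 0.991
```

The phantom plants a 0–6 s lag field with the sinus seed at the downstream
end; at an sLFO-to-noise amplitude ratio of 4 the seed-based map recovers it
to within one TR everywhere, and the two estimators agree voxel by voxel at
r = 0.99 (their constant offset — Lag-rec is anchored to the global-signal
phase, Lag-SSS to the sinus — does not affect the correlation).

Reliability of two noisy replicates of a map:

```r
icc_between(m$values, m$values + rnorm(4096, sd = 0.3), run$brain_mask)
#> ICC(A,1) [mcgraw_wong] = 0.9871 (printed: 0.9871); band: excellent
#>   MS meas 8.264e-05, MS obj 6.812, MS err 0.04433 (k=2, n=2744)
```

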