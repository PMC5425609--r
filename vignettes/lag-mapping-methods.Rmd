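---
title: "Hemodynamic lag mapping on synthetic BOLD phantoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemodynamic lag mapping on synthetic BOLD phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Circulating blood carries a systemic low-frequency oscillation (sLFO,
roughly 0.01–0.1 Hz) that is visible in the BOLD signal everywhere the blood
goes.  Because the oscillation travels with the blood, its arrival time
differs across the brain by several seconds: early in arterial territories,
late in the draining veins.  Cross-correlating each voxel's time series
against a reference extracts a voxelwise *lag map* — a picture of relative
blood transit.  This package implements the two standard estimators of that
map, the ICA-based denoising heuristic whose interaction with the lag signal
is the scientific question, the reliability statistics used to compare them,
and a synthetic 4D phantom that makes the whole chain testable against known
ground truth, which no in vivo dataset can provide.

`boldlag` is organized as an analysis workflow: all computation lives in the
package functions, and the numbered scripts under `analysis/` are thin
narrative drivers that run the experiments and write tables under
`results/`.

## The phantom's generative model

Each in-mask voxel $v$ of a run is assembled as

$$y_v(t) = 100 + a(v)\, s\!\left(t + L(v)\right) + n_v(t)$$

where $s$ is one shared band-limited Gaussian series (the sLFO), $L(v)$ is
the planted lag field (**positive = upstream = earlier arrival**), $a(v)$ is
an amplitude map that decays toward upstream voxels, and $n_v$ collects the
structured and unstructured noise:

* gray-matter *network* fluctuations (two disjoint two-block networks with
  independent 0.01–0.1 Hz series) and an HRF-convolved task response in a
  designated task region — the "neuronal" content;
* a *cardiac* sinusoid (plus first harmonic) on a vessel/CSF footprint;
* a *respiratory* oscillation (~0.25 Hz, amplitude-modulated) whose spatial
  footprint alternates sign between adjacent slices, emulating
  multiband/motion artifacts;
* low-order *drift* on a brain-edge footprint, and white noise;
* for breath-hold events, a global response with a small neurovascular peak
  near 5 s followed by a larger, delayed vasodilatory peak.

Signals are generated on a fine grid (`oversample = 20`, i.e. 40 Hz at
TR = 0.5 s) and then sampled at TR.  This matters: a 1 Hz cardiac rhythm
sampled at TR = 0.5 s sits exactly at the Nyquist frequency, and decimating
the sampled data folds it to low apparent frequencies.  Without a
supra-Nyquist continuous model the decimation experiments would be
meaningless.

Key defaults (`phantom_config()`): TR 0.5 s, 624 frames per run, 16³ voxels
of 4 mm, sLFO band 0.01–0.1 Hz with unit amplitude, cardiac 1.0 Hz,
respiratory 0.25 Hz, white-noise SD 0.25 (an sLFO-to-noise amplitude ratio
of 4).  All amplitudes are percent-signal-change-like relative to the
baseline of 100.

### The lag field and its reference

A lag map is only defined relative to a reference.  The phantom's reference
is the sinus seed (`sss_seed`), placed at the most downstream end of the
field, so the default gradient field spans 0 to +6 s *relative to the
sinus*: almost all brain voxels are upstream of the draining vein, hence
positive.  The declared admissible range remains −4…+6 s — the grid of the
map itself — and `make_lag_field()` called with an explicit range spans it.
Planted lags are snapped to the TR grid by default because the estimators
are TR-discrete by construction; the `tree` style derives lags from graph
distance to the sinus through the mask with a smooth random perturbation.

The recursive tracker's zero, by contrast, is the phase of the global-signal
seed, not the sinus.  `lag_truth_stats(..., align = "median")` therefore
aligns an estimate to the truth by the median integer-TR offset before
computing voxelwise error; correlations are offset-invariant either way.

### What the generator does *not* emulate

No anatomy, no head motion, no slice timing, no spatial normalization, no
susceptibility artifacts; tissue maps are crisp blocks; the sLFO propagates
by pure translation (an optional `dispersion` mode low-pass filters the
waveform progressively with distance upstream, reproducing the amplitude
decay of the recursive seed traces).  Passing tests on the phantom therefore
demonstrates the *mechanics* of the estimators — recovery, polarity,
aliasing, classification — not their performance under realistic artifact
loads.

## Preprocessing

`temporal_filter()` is realized as Fourier-domain masking, which is
zero-phase by construction: lag estimates must not inherit a time shift from
the filter.  It is exactly idempotent, and the band edges (high-pass
0.008 Hz; band-pass 0.008–0.16 Hz for mapping) are the conventional ones.
`normalize_concat()` drops the first 20 volumes of each run, normalizes
every voxel to zero mean and unit variance per run, then concatenates —
order fixed.  `decimate_run()` keeps every *k*-th frame with deliberately no
anti-alias filter; offset 0, configurable.

## ICA denoising

`decompose_ica()` performs spatial ICA (FastICA on a PCA-whitened basis) so
that components are spatial maps and the mixing matrix gives time courses,
which is the orientation the feature set needs.  Dimensionality estimation
is out of scope; phantoms use K = 12–15, roughly twice the number of
planted processes, which lets the decomposition isolate each planted source
while absorbing the lag-shifted sLFO copies into a handful of components.

Three features per component:

* `hf_ratio` — integrated periodogram power above 0.2 Hz divided by power
  at or below (mean periodogram, no taper, z-scored series; threshold
  sentence uses the ratio, the *fraction* is available via a flag);
* `nongray_index` — the map is smoothed at 8 mm FWHM, z-scored over the
  mask, thresholded at |z| > 1, and the weighted tissue mask
  (GM + WM)/2 averaged over suprathreshold voxels is subtracted from 1
  (division by 2 compensates partial-volume dilution);
* `slice_dependency` — mean non-DC spatial Fourier power along Z divided by
  the same along Y.

`classify_components()` labels a component noise when **any** active feature
exceeds its threshold: Dn1 (ratio > 0.6), Dn2 (adds non-gray > 0.6,
slice > 4), Dn3 (ratio > 0.4, tissue 0.5, slice > 3), plus a
slice-dependency-only level.  Two readings of the Dn3 tissue cutoff exist
because it is stated as a *gray-matter* index where the other levels use the
*non-gray* index; the default is the complementary non-gray reading
(`nongray > 0.5`), the literal gray-index reading sits behind
`dn3_gray_reading = TRUE`.  The slice-only level has no stated cutoff and
borrows Dn2's 4.

`remove_components()` regresses every voxel on **all** component time
courses jointly and subtracts only the fitted contribution of the
noise-labeled ones (non-aggressive removal: shared variance survives).  With
orthogonal time courses this is exactly a projection and can never increase
voxel variance; estimated ICA time courses are near-orthogonal, so the
property holds to numerical tolerance.  Removing the *signal*-labeled
components of the Dn3 classification instead yields the noise-only dataset.

On phantoms the sLFO carriers have heavy CSF involvement and are caught by
the tissue feature at Dn2/Dn3 — which is exactly the mechanism by which
aggressive denoising destroys lag information while the noise-only dataset
retains it.  The phantom's sLFO is more CSF-weighted than a real brain's, so
this collapse happens one level earlier than in vivo; the directionality is
the tested property, not the level at which it occurs.

## Lag mapping

`lagged_correlogram()` computes overlap-truncated Pearson correlations (no
padding, minimum overlap 10 frames) between each voxel and the reference
advanced by each shift; a voxel leading the reference by $d$ seconds peaks
at $+d$.  `lag_sss()` takes the sinus-ROI mean as reference, searches
−4…+6 s at TR steps, breaks argmax ties toward the smallest |shift| (toward
the null rather than the range edge), and smooths the map at 8 mm FWHM with
invalid voxels excluded from the kernel.  `lag_rec()` starts from voxels
whose correlogram against the global mean peaks at zero shift (≥ 0.2),
then recursively admits unassigned voxels with a strict local correlogram
peak at ±TR against the current seed mean, each voxel assigned at most once,
out to ±4 s; every step records the seed's mean series and amplitude.
Correlogram peaks below 0.2 are discarded, which leaves holes.

`fill_holes()` solves the Laplace equation over the holes with valid voxels
as Dirichlet boundary, by relaxation.  Each hole relaxes to the mean of its
6-neighbours using only axes with *both* neighbours available — one-sided
axes are dropped — so affine fields are reproduced exactly and every update
is a convex average, which enforces the maximum principle.  A voxel with no
complete axis pair (a mask corner) falls back to the available-neighbour
mean and is the one place affine exactness is not guaranteed; real
correlogram holes are isolated interior voxels, where the guarantee holds.

A caveat found while validating: on a *time-shuffled* run the lag map is
destroyed as it should be, but the truth correlation does not fall fully to
zero, because zero-shift correlations survive a common permutation and still
order voxels coarsely by lag proximity to the seed.  The map itself (lags
within one TR of truth) collapses from ~100% to ~30%.

## Reliability statistics

`icc_a1()` computes the two-way ANOVA mean squares from row, column and
grand means and the absolute-agreement single-measure ICC with measurements
as rows (k) and objects as columns (n):

$$\mathrm{ICC} = \frac{MS_{obj} - MS_E}
{MS_{obj} + (k-1)MS_E + \tfrac{k}{n}(MS_{meas} - MS_E)}$$

A variant in which the measurement term enters the denominator with a minus
sign appears in print in parts of this literature; it is available as
`formula = "printed"`, both values are carried in every result, and the
default is the standard form above.  `icc_between()` arranges two maps as a
2 × voxels matrix (FC seed regions excluded via `exclude`);
`icc_within_map()` computes the per-voxel measurements × subjects ICC map.
Qualitative bands: < 0.2 poor, 0.2–0.39 fair, 0.4–0.59 moderate, 0.6–0.79
good, ≥ 0.8 excellent.  `image_similarity()` ("image preservation") is
Pearson correlation over the mask by default, with an ICC-based reading
selectable, since no operational definition is canonical.
`friedman_test()` wraps the standard rank test with a degenerate-input
guard (identical columns → statistic 0, p = 1).

## Sampling-rate experiments

`decimate_run()` + `alias_frequency()` implement the aliasing analysis.
With cardiac exactly at 1.0 Hz, decimation by 2 folds it exactly to DC,
which mean-removal deletes — a measure-zero special case that would hide the
mechanism under study.  The sampling-rate analysis therefore runs its
phantom at 0.97 Hz (≈ 58 bpm, a realistic resting heart rate) with strong
pulsatile amplitude (2, typical of unfiltered CSF/vessel signal): at
effective TR 1 s the alias lands at 0.03 Hz, inside the sLFO band, and the
lag map degrades; at TR 1.5 s it lands at 0.30 Hz, outside the 0.16 Hz
low-pass, and the map survives.  Where the nominal 0.16 Hz band edge exceeds
the decimated Nyquist frequency (factors ≥ 7) the sweep clips it to just
below Nyquist.

## Event-locked averaging

`select_isolated_events()` keeps events with ≥ 9 s to the previous and
≥ 15 s to the next event (run boundaries as virtual neighbours).
`timelocked_average()` aligns epochs to the nearest frame over a −5…+25 s
window, baseline-corrects against the pre-onset mean (a choice, on by
default), averages within subject and grand-averages across subjects with a
t-based 95% band.  The event-averaging experiment uses 10 runs of 320 s
standing in for a 10-participant grand average, which yields ~80 isolated
events; recovery of the planted HRF is evaluated over 0–15 s post onset
against the HRF convolved with the event box, because isolation is only
guaranteed 15 s past onset — beyond that the next trial's response may enter
the window.  The 1/√N attenuation of the random-phase sLFO is measured as
the mean over 150 independent runs of the per-run RMS ratio; within a run,
isolated events are spaced near the band's coherence time, which depresses
the ratio slightly below 1 (≈ 0.91 in expectation) — well within the 20%
band around the law, and the reason a single run is not used as the
estimate.

## Problem sizes and numerical choices

Phantom experiments run on 16³ grids with 600–1248 frames; ICA uses K = 12
–15; classification recall is estimated over 20 independent phantoms with
heart rate drawn uniformly in 0.9–1.05 Hz (inter-individual variation);
Laplace relaxation stops at a 10⁻¹⁰ maximum update; variance-components
checks use 2 000 simulated 2 × 20 matrices.  These sizes were chosen so the
whole chain, including the acceptance run, completes in minutes on one CPU
while every statistic sits far from its decision boundary.

## Known limitations

* The phantom geometry is abstract; tissue-feature behaviour on real partial
  volumes will be less crisp than on block phantoms.
* The recursive tracker's discrete ±TR stepping can merge adjacent lag
  levels when the planted field has ties on the TR grid and the initial seed
  straddles two of them; on continuous in-vivo-like fields this appears as
  ordinary quantization error.
* ICC values are computed per the single-measure absolute-agreement form
  only; consistency and average-measure forms are out of scope.
* No head motion or motion correction is modeled, so the slice-dependency
  feature is exercised only by the planted slice-alternating footprint.
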