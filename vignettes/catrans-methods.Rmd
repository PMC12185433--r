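---
title: "Models and methods behind catrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind catrans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catrans)
```

`catrans` analyses somatic two-photon calcium imaging: it detects discrete
calcium transients in per-cell ΔF/F traces, counts them in 5-minute
windows, and compares groups of neurons over time. This vignette documents
the models, the tunable parameters, and the numerical and design choices in
each stage — in particular the places where the published recipe leaves
freedom and this package had to choose.

## The synthetic session generator

No public raw movies exist for this class of experiment, so the package
ships a generator whose output has the statistical structure the analysis
assumes, with complete ground truth. It is first-class, tested code — every
benchmark in the test suite and the acceptance script runs on it.

A session (`session_spec()`) is defined by per-window event rates, the
frame interval (default 0.249 s, ~4 fps, so a 300-s window is 1205
frames), a baseline luminance `baseline_f0`, noise and drift amplitudes,
and a seed. Each cell's raw luminance is

> baseline + drift + amplitude · (events ⊛ kernel) · baseline + noise

where:

- **Kernel** (`transient_kernel()`): a difference of exponentials with rise
  0.05 s and decay 0.4 s, unit-normalised at its peak — the standard
  fast-indicator (GCaMP6f-like) impulse response. The discretised kernel is
  0 at onset, peaks once, and decays by `exp(-dt/decay)` per frame in the
  tail. The default amplitude is 1.0 ΔF/F: a soma-scale burst transient.
  Single action potentials are smaller, but the windowed-count analysis
  targets burst-scale events, and at a 5-frame (1.25-s) smoothing width a
  much smaller or faster transient would not survive the published
  threshold in the first place.
- **Event times**: homogeneous Poisson within each 300-s window, with the
  rate varying across windows (default 6 events/window; the two-group
  benchmarks double the third window — the 11–15-min peak — in the treated
  group). A trailing partial window gets its rate scaled by its fraction of
  300 s.
- **Noise**: additive Gaussian, default SD 5 luminance units on a baseline
  of 100, i.e. 5% — which puts the default transient at 20× the per-frame
  ΔF/F noise, a good-SNR soma recording.
- **Drift**: one slow sinusoid over the session, default amplitude 2% of
  baseline, with a random per-cell phase. It exercises the median baseline
  and the flat-baseline validation without dominating them.
- **Seeding**: the master seed deterministically derives one RNG substream
  per cell plus one session-level stream, so equal seeds give bit-identical
  sessions and the generators leave the caller's RNG state untouched.

`simulate_movie()` renders the same session spatially: each cell is an
isotropic Gaussian footprint (SD 3 px, truncated at 3 SD — arbitrary but
fixed; only relative intensities matter to disk-ROI means) whose peak
follows the cell's clean trace, on a dim background, with noise added once
at the pixel level and optional per-frame rigid jitter recorded in the
ground truth. Default geometry is a 16-px grid, which keeps neighbouring
5-px ROIs disjoint; overlapping or out-of-field cells are rejected rather
than rendered.

What the generator deliberately does *not* model: spike-to-calcium
nonlinearity, bleaching, neuropil contamination, and z-motion. Passing
benchmarks on this generator therefore shows that the pipeline implements
its stated rules correctly and recovers rates under its stated noise model
— not that it is robust to neuropil cross-talk or axial drift in real
recordings.

## Motion correction

Per-frame rigid translation is estimated by FFT cross-correlation against a
template, by default the mean of the first 100 frames (`estimate_shifts()`
also accepts an explicit template). Two numerical choices matter:

- **Unnormalised cross power spectrum.** The classic phase-correlation
  variant whitens the spectrum; on small, sparse fields (a handful of
  Gaussian somata on a dim background) that hands noise-dominated high
  frequencies equal weight, and subpixel accuracy degrades several-fold.
  The matched-filter (unnormalised) correlation is what the contract
  actually asks for — the shift that maximises cross-correlation with the
  template — and recovers injected integer shifts exactly and ±0.5-px
  subpixel shifts to well under 0.1 px RMSE under noise.
- **Subpixel refinement** evaluates the correlation surface on a ±1-px
  neighbourhood of the integer peak at 0.1-px spacing with an explicit
  local DFT (no zero-padded giant FFT), and magnitudes are capped at
  `max_shift_px`.

Estimated shifts are defined *relative to the template*: if the early
frames are themselves displaced, the whole series carries that constant
offset. `apply_shifts()` resamples each frame at the shifted coordinates —
exact for integer shifts, bilinear for fractional ones — and fills
out-of-field pixels with the frame median so border ROIs are not biased
toward zero. An all-constant movie has no registration information; it
returns zero shifts with a warning.

## ROI extraction and ΔF/F

An ROI is every integer pixel within Euclidean distance `radius_px`
(default 5) of the selected center — 81 pixels for an interior radius-5
disk — compared on squared terms so membership is exact; edge masks are
clipped with a warning. The pooling statistic is the **mean** over mask
pixels (the published description names the pixel set but not the
statistic; the mean is the soma-ROI convention, and any fixed linear
pooling cancels in ΔF/F anyway).

ΔF/F uses the per-cell **median over all frames** as `F0`, which makes
each ΔF/F row median-zero and gain-invariant (both asserted to 1e-12 in
the tests). The per-cell SD that scales the detection threshold is taken
from the full, unsmoothed ΔF/F series with events included — the
published rule names no exclusion window, and this choice makes the
threshold mildly activity-dependent (see "known limitations"). Cells whose
median fluorescence is not positive have no defined ΔF/F; they are
excluded and reported, not silently dropped.

## Event detection and validation

Detection runs on the 5-frame centered moving average (the published
ordering applies smoothing before thresholding), with the window truncated
at the series edges. Candidates are upward crossings of
`z_threshold × sd_cell` (default 1.96) with hysteresis: once above
threshold, no new onset until the smoothed trace falls back below. This
prevents one transient from being counted repeatedly; the rule is simple
enough that the test suite checks it against an exhaustive frame-by-frame
scan on every trace it generates.

Validation asks whether the candidate looks like a genuine transient:

- an 8-frame (~2-s) baseline, every sample within ±1 SD of zero;
- a 3-s response window (`round(3 / dt)` = 12 frames at 0.249 s) whose
  mean must exceed the baseline mean (transients are positive-going — dips
  are never validated);
- a two-sided Welch two-sample t-test of response vs baseline samples at
  `alpha = 0.05`. The Welch form avoids the equal-variance assumption,
  which is clearly violated between a quiet baseline and a decaying
  transient; the p-value is computed in closed form and is tested for
  equality against `stats::t.test()`.

Two numerical choices deserve emphasis, because the naive reading fails:

- **Both validation windows are taken from the smoothed trace.** On the
  raw trace, a fast-decaying transient spends most of the 3-s response
  window back at baseline, so the response variance grows with the
  transient amplitude and the two-sample t statistic converges to an
  amplitude-independent constant near 2 — the test then rejects the bulk
  of perfectly clean events. Smoothing the local trace makes the response
  window coherent and restores near-complete validation of clear events
  while leaving the false-positive control intact.
- **The baseline window ends one smoothing half-width (+1) before onset.**
  A centered 5-frame smoother leaks the transient 2 frames backwards; with
  the baseline ending at `onset - 1` the leak alone pushes the last
  baseline samples past the 1-SD bound and vetoes every true event. The
  2-frame guard gap makes the baseline causally uncontaminated.

Events whose onset lacks room for the baseline (or whose response window
runs past the session) are discarded with a reason code. Counting assigns
each validated event to the window containing its onset time — half-open
intervals `[k·300, (k+1)·300)` — and events past the last complete window
are dropped and reported. A response window may straddle a boundary; onset
time alone decides membership, one unambiguous rule.

## Group statistics

The two-group layer reproduces the conventional gating: Shapiro–Wilk on
both samples; if both pass, an F-test of variances (α = 0.05 — the
simplest rule compatible with "significantly different SDs") chooses
pooled-variance t vs Welch t; otherwise Mann-Whitney U. Effect sizes are
Cohen's *d* on the pooled SD and rank-biserial `r = 2U/(n1·n2) − 1`. No
multiple-testing correction is applied anywhere — the statistics layer
reports raw p-values, as the source analyses do.

`mixed_anova()` treats each **cell as a subject** (the experimental n of
this design is neurons, not animals): group is between-subjects, window is
within-subjects, fitted via `aov()` with an `Error(cell)` stratum. The
between-subjects group test then has df `(g − 1, N − g)` — (1, 304) for
161 + 145 cells, (1, 37) for 15 + 24 — and partial η² uses each effect's
own stratum error. No sphericity correction is applied to the within
factor (uncorrected df are assumed; with 4 windows and count data the
correction would be minor, and the printed design df are uncorrected).
The test suite checks the whole decomposition against explicit textbook
sums-of-squares arithmetic, and a null simulation confirms the group test
holds its 5% size on Poisson counts.

`kruskal_wallis_test()` reports tie-corrected H with df k − 1 and the
eta-squared effect size `(H − k + 1)/(n − k)` (its denominator df, n − k,
is 35 for four groups of 10/10/10/9). Multi-group software sometimes
prints an F alongside such designs, so the Welch one-way ANOVA F is
returned as a companion statistic; the two are computed independently and
neither is asserted to be the other.

`percent_change()` is plain per-window arithmetic against a named
reference group, erroring (not NA-ing) when a reference mean is zero.
`cumulative_dose()` sums a titration schedule up to the triggering
injection; `ptz_schedule()` encodes the standard ramp (initial dose, two
5 mg/kg boosters 10 min apart, 10 mg/kg every 5 min thereafter), so Grade V
at the third injection of a 40 mg/kg schedule is 50 mg/kg.

## Benchmark scale and known limitations

The acceptance script and test suite run the stochastic benchmarks at 100
cells/group, 50 seeds for the two-group recovery and 200 replicates for
the null-size check — sizes at which the binomial error of the measured
rates is a small fraction of the bands being checked, while the whole
suite stays interactive.

Known limitations, all visible in the benchmarks rather than hidden:

- The detection threshold scales with the full-trace SD, which grows with
  activity. More active cells therefore run slightly conservative
  thresholds, and a true 2× rate ratio is measured as ~1.8–1.9× end to
  end (well within the 20% recovery band, but a real compression — worth
  remembering when interpreting percent changes).
- Hysteresis merges transients closer than the smoothed supra-threshold
  excursion (~1–2 s), and the flat-baseline rule vetoes events that ride
  on the tail of a predecessor; both cause a few percent of misses at the
  default rates (detection F1 ≈ 0.95 at the default SNR).
- Validation power collapses below roughly 5× ΔF/F noise amplitude, by
  design of the published rule — the acceptance benchmarks run at
  burst-scale amplitude where the procedure is meant to operate.
- The ANOVA treats counts as approximately normal within cells; at the
  default rates (Poisson means ≥ 6) this is comfortable, and the null
  simulation confirms the size, but very sparse regimes would call for a
  GLMM instead.
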