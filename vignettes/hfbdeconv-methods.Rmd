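---
title: "Deconvolving blink- and gap-related HFB responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving blink- and gap-related HFB responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfbdeconv)
```

## The scientific problem

During a continuously presented visual stimulus, both eye blinks and brief
experimenter-inserted blank frames ("gaps") interrupt the retinal input for
on the order of 100–200 ms. Intracranial recordings show that the 70–150 Hz
high-frequency broadband (HFB) envelope — a proxy for aggregate local
spiking — reacts to these interruptions with two stereotyped components: a
negative *activation dip* after the stimulus disappears and a positive
*reappearance overshoot* after it returns. The analytic difficulty is that
these responses ride on top of, and overlap with, the much larger response
to the 1 Hz stream of object images, and consecutive events overlap each
other. This package implements the full analysis chain that isolates and
quantifies these components, together with a synthetic-session generator
with known ground truth so that every stage is testable end to end.

## HFB extraction

Raw multichannel recordings (500 Hz; 512 Hz inputs are resampled) are
re-referenced to the common average of non-excluded channels. The 70–150 Hz
range is split into eight contiguous 10 Hz bands; each band is band-pass
filtered with a zero-phase (forward–backward) FIR filter, the magnitude of
its analytic signal is taken, and each band envelope is divided by its own
temporal mean before the eight are averaged. The per-band normalization
weights the bands equally despite the 1/f amplitude spectrum of the field
potential. The result is downsampled to 250 Hz and converted to percent
signal change, `100 * (x / baseline_mean - 1)`, with the inter-block gray
baselines defining 0%.

Numerical choices: the FIR order defaults to `2 * round(1.5 * rate / bw)`
where `bw` is the 10 Hz band width, giving a transition band comparable to
the pass band — narrow enough that adjacent bands are well separated (a
short order keyed to the band's low edge, as in some EEG tooling, lets
neighbouring components beat against each other and blurs amplitude
modulation). The filter family is a windowed-sinc FIR applied two-pass;
the order is configurable. Downsampling applies an anti-alias low-pass to
the envelope before decimation.

The outlier scan z-normalizes each channel's first difference, takes the
across-channel median of the absolute z-scores, flags timepoints where the
median exceeds 2, and dilates the flags by ±200 ms. The median makes the
rule sensitive to widespread (recording-system) artifacts while ignoring
single-channel events. Note that the rule presumes most channels are not
task-responsive: in a montage consisting solely of strongly visual sites, a
shared evoked transient can trip it. The synthetic montages therefore
include non-responsive sites, as clinical implants do. The z statistics are
global over the recording (a per-segment variant is not implemented).

## FIR deconvolution with HC3 errors

The HFB timecourse is modeled as a linear superposition of event-locked
responses, each expressed as a train of non-overlapping 4 ms unit pulses
(one FIR predictor per lag): stimulus onsets over a [0, 1500) ms window
(375 columns at 250 Hz) and interruption events over a [−250, 500) ms
window (187 columns), the latter locked either to the interruption onset
(disappearance) or offset (reappearance). Windows are half-open and a
trailing partial bin is discarded. Onset- and offset-locked interruption
predictors are fitted in *separate* models: with occlusions of only
100–200 ms the two pulse trains are nearly collinear, and a combined model
is unstable (it exists for the noiseless validation tests, where it is
exact). Excluded timepoints — animal-target trials, outlier-masked samples,
rest breaks — receive one dummy unit-vector column each; since a dummy
saturates exactly its own timepoint, dropping those rows is numerically
identical for every FIR coefficient, and the package uses row-dropping as
the fast path inside permutation and split-half loops (`exclusion_mode =
"drop"`; the equivalence is asserted in the test suite). No global
intercept is fitted: baseline normalization defines the zero level.

Coefficients are the OLS solution `(X'X)^-1 X'y`, computed by a pivoted
Cholesky factorization of the sparse normal equations; exactly collinear
columns are dropped with a warning rather than regularized, so the printed
estimator remains the contract. Standard errors use the HC3
heteroskedasticity-consistent sandwich
`(X'X)^-1 X' diag[e_i^2/(1-h_ii)^2] X (X'X)^-1`: unlike homoskedastic
errors they reflect the variability of the particular samples that inform
each lag. Saturated timepoints (leverage 1) have identically zero residuals
and contribute nothing to the sandwich; a leverage of 1 with a nonzero
residual is impossible for a valid fit and raises an error. Per-lag z
statistics (`beta/se` against a standard normal) are FDR-adjusted across
lags within each trace at `q = 0.05 / n` visual electrodes of the patient.

The naive alternative — event-locked averaging — is implemented for
comparison (`template_subtract_average`). Its template spans one trial
period (1000 ms) rather than the 1500 ms FIR window: templates then tile
each block, whereas subtracting a longer template at every onset would
remove the next trial's onset response twice. Averaging *pseudo-events*
placed in interruption-free trials without template subtraction exposes the
overlap artifact that deconvolution removes; this demonstration is part of
the acceptance suite.

## Component quantification and the split-half estimator

The dip is the contiguous run of strictly negative timepoints after the
disappearance (lags ≥ 0 of the onset-locked trace) with the largest
absolute integral (`sum(beta) * dt`, %·s); the overshoot is the analogous
strictly positive run of the offset-locked trace. Zeros terminate runs;
ties go to the earliest run. Choosing the extreme cluster on the same trace
that is integrated inflates the estimate under noise (selection bias /
circular analysis). The unbiased estimator halves each interruption event
set into two predictor sets within one model, determines the cluster
interval on one half's trace and integrates the other half's trace over
that interval, and averages over 30 random splits (odd counts split
⌈n/2⌉/⌊n/2⌋). The package averages the two measurement directions within
each split (A selects / B measures and vice versa), which preserves
unbiasedness and reduces split noise. Halving is stratified within each
interruption-by-category cell.

## Inference

*Electrode level.* Gap versus blink differences in a component are tested
by permutation: gap/blink labels of the individual events are shuffled
while keeping the label counts within face and within non-face trials
fixed, the reduced model (no category split) is re-fitted, and the
component difference recomputed; with `b` permutations at least as extreme
as the observed difference out of `m` (default 2000), `p = (b+1)/(m+1)`,
doubled for two-tailed testing. Observed and permuted data share the same
cluster selection, so selection bias cancels. Both directional tails are
reported; FDR adjustment (Benjamini–Hochberg step-up, via `p.adjust`) is
applied across the visually responsive electrodes.

*ROI level.* Non-uniformity of the proportion of significant electrodes
across the seven ROIs is measured by `chi2 = sum((O_i - E_i)^2 / E_i)` with
`E_i = n_i * sum(O) / sum(n)` and tested against a randomization null that
reassigns the significant flags across ROIs with the ROI sizes and the
total number of flags fixed (multivariate hypergeometric, default 10000
draws, smoothed p). An all-zero table is defined to have statistic 0. The
mixed-effects group model consuming the split-half component table is out
of scope; `export_component_table()` writes that table, optionally with the
positive-shift + log transform used for variance stabilization in such
fits.

## Blink detection and timing

A blink is registered only when a pupil-tracking loss co-occurs (within
±100 ms, configurable) with a super-threshold EOG artifact; pupil losses
without EOG support (tracking dropouts) flag their trials as ambiguous.
Onset is the time of peak second-derivative magnitude of the pre-loss
pupil decrease (central differences on a 10 ms-smoothed trace — raw
differentiation of the quantized pupil signal is unusable; the smoothing
window's edge samples are excluded from the search, and the
one-sample lag of the double difference is corrected). "Peak acceleration"
is interpreted as the extremum of the second-derivative magnitude during
the decrease. If the loss is instantaneous, onset falls back to the last
valid sample. Offset mirrors this on the post-reacquisition increase.

EOG-only timing fits each ±750 ms segment with a degree-5 polynomial
baseline plus a trapezoid. The trapezoid's start, rise, plateau and fall
are the nonlinear parameters (bounded Levenberg–Marquardt with three
starts); its height and the polynomial coefficients enter linearly and are
profiled out at each step, which makes the fit fast and robust. After
baseline subtraction the trace is thresholded at a fraction of the fitted
height — 22% by default; `calibrate_eog_threshold()` re-derives the
fraction from sessions with both modalities by minimizing the error in
predicting pupil-derived durations (ties resolve to the smallest tested
fraction). EOG artifact polarity is assumed positive; orient the channel
before fitting if necessary.

Post-hoc matching of gaps and blinks by onset latency (tolerance 50 ms) or
duration (15 ms) is incremental: each iteration adds the eligible pair
that, after inclusion, minimizes the absolute difference between the means
of the paired gap and blink values; ties break by the smallest pair
difference, then the earliest gap. The matching objective could also be
read as a single global optimization; the incremental greedy reading was
chosen and is what the tests pin down.

## Electrode screening

Per electrode, trial responses (mean HFB 50–350 ms after each non-target
trial onset, requiring no interruption from 100 ms before the window to its
end) are compared with baseline by a one-sided Wilcoxon rank-sum test,
Bonferroni-corrected within patient. The baseline observations entering the
test are per-interval means, not raw samples: raw 250 Hz samples are
strongly autocorrelated and would inflate the effective n. The effect size
is Glass' Δ of the best-responding category, using the SD across baseline
interval means; electrodes with corrected p < 0.05 and Δ ≥ 2 are retained.
Face selectivity requires face > each other category at p < 0.05 per
contrast, uncorrected. ROI labels are inputs (anatomical parcellation is
out of scope); face-selective electrodes override their anatomical label
and join the FC ROI, and `unassigned` electrodes are excluded from
ROI-level analyses only.

## The synthetic-session generator

The generator emulates the task: 32 blocks of ten 1 s images (faces,
non-faces, animal targets) separated by 3 s gray baselines; gaps in 60% of
the trials of non-voluntary blocks at 350/550/750 ms with durations uniform
in 100–200 ms, carrying black/gray and abrupt/gradual labels (the labels
scale kernel amplitudes only — no optics are simulated); cued ~1 Hz
voluntary blinks in 12/32 of blocks; spontaneous blinks as a Poisson
process. The task's design constants are the defaults of
`sim_config()`. Quantities the task does not fix were chosen once:
spontaneous blink rate 0.25/s (a typical resting rate), blink durations
truncated log-normal centred near 150 ms (spontaneous) and 200 ms
(voluntary), voluntary blink latency a truncated normal around mid-trial.
Blinks never overlap gaps within a trial.

Sessions exist in two fidelity tiers. The *HFB tier* renders each
electrode's timecourse as an exact linear superposition of ground-truth
kernels (stimulus kernels per category; disappearance and reappearance
kernels per interruption type) plus AR(1) noise (coefficient 0.9, SD 1% —
positively autocorrelated like real HFB; 1/f noise is available). Exact
linearity makes noiseless deconvolution recovery testable to numerical
precision. The *raw tier* renders the same profile as the amplitude
modulation of a 70–150 Hz carrier on 1/f background at 500 Hz, for testing
envelope extraction; the default carrier is a deterministic multisine (one
component per sub-band), whose stable instantaneous envelope lets AM
recovery be scored cleanly — band-passed noise carriers (closer to a real
field potential) are available but their stochastic envelope caps the
attainable correlation. The default kernel set encodes the hierarchical
dissociation the pipeline is built to detect: early ROIs (V1–V3) dip and overshoot for gaps and
blinks alike, with blink dips deeper than gap dips (markedly for voluntary
blinks); high-level ROIs (V4, VO, FC, N-FC) overshoot for gaps only.
A single multiplicative gain per electrode varies amplitudes without
flipping true effect directions, and `unassigned` electrodes are silent.

Ocular channels: the pupil trace descends through a logistic eyelid ramp
(time constant 15 ms), is lost while occluded, and reopens symmetrically;
the analytically known peak-curvature times of the measurable segments are
stored as timing ground truth. The EOG is a degree-5 polynomial drift plus
a per-blink trapezoid whose half-height width equals the blink duration,
plus white noise.

What the generator does not emulate: saccades and gaze shifts, interictal
spikes, retinal/optical nonlinearities, non-stationary noise, and
electrode-to-electrode noise correlations. Passing tests therefore
demonstrate the correctness and calibration of the *procedures* under the
stated model, not robustness to everything real recordings contain.

## Problem sizes and reproducibility

Simulation-based validation runs at a coarse analysis tier chosen for
desk-scale iteration: 25–50 Hz grids (20–40 ms FIR bins) and sessions of
4–32 blocks, with the 250 Hz / 4 ms tier exercised where exactness is the
point (design dimensions, noiseless recovery). The calibration studies use
on the order of 50–200 simulated null electrodes, permutation counts of
300–500, and the full 32-block session length for the end-to-end
directional reproduction. Every stochastic step takes an explicit seed, and
`run_pipeline()` derives all stage seeds from one global seed, so identical
configurations reproduce bit-identical outputs. Patient-data effect
magnitudes (group F statistics, exact significant-electrode counts) are
not reproducible from synthetic sessions at these scales and are not
targeted; the qualitative hierarchy — overshoot differences concentrated
in high-level ROIs, blink-deeper dips with no inverse effects — is.

## Known limitations

- The permutation stage re-estimates plugin components on the reduced
  model rather than re-running the split-half procedure; the selection
  bias is symmetric between shuffled groups, which preserves validity and
  is far cheaper, but the permuted statistic is not the unbiased one.
- The EOG trapezoid fit assumes a single blink per ±750 ms segment;
  overlapping blink artifacts within a segment can misfit.
- `detect_blinks_pupil` requires a pupil loss; partial blinks that never
  drop tracking are not detected.
- The chi-squared randomization test conditions on the observed totals; it
  does not model patient identity (the out-of-scope mixed-effects analysis
  addresses generalization across patients).
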