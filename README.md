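# hfbdeconv

Deconvolution and quantification of blink- and gap-related high-frequency
broadband (HFB) responses in intracranial recordings.

## The problem

During continuous visual stimulation, the retinal input is briefly cut
hundreds of times an hour by eye blinks, and can be cut experimentally by
blank video frames ("gaps") of comparable duration. The 70–150 Hz HFB
envelope of the field potential — a proxy for local population spiking —
responds to such interruptions with a negative **activation dip** after the
stimulus disappears and a positive **reappearance overshoot** after it
returns. Whether and where these components differ between blinks and gaps
speaks directly to how the visual system maintains perceptual continuity
across blinks. The analytic obstacle is overlap: interruption responses ride
on the much larger responses to the 1 Hz stream of object images and on each
other.

`hfbdeconv` is for electrophysiologists who need this analysis chain as
tested, reusable code: HFB extraction from raw multichannel recordings,
blink detection and timing from pupil/EOG traces, FIR deconvolution of
overlapping responses, unbiased dip/overshoot quantification, and
permutation/randomization inference — plus a synthetic-session generator
with known ground truth that exercises every stage end to end.

## The model at the core

The HFB timecourse *y* (percent signal change, 250 Hz) is modeled as a
linear superposition of event-locked finite impulse responses: for each
predictor set (stimulus onsets over lags [0, 1500) ms = 375 columns;
interruption onsets or offsets over [−250, 500) ms = 187 columns) the design
matrix *X* holds one 4 ms unit pulse per event per lag. The per-lag response
is the OLS estimate

&nbsp;&nbsp;β̂ = (XᵀX)⁻¹ Xᵀy,

with HC3 heteroskedasticity-consistent standard errors

&nbsp;&nbsp;Var(β̂) = (XᵀX)⁻¹ Xᵀ diag[eᵢ²/(1−hᵢᵢ)²] X (XᵀX)⁻¹,

where *eᵢ* are residuals and *hᵢᵢ* the hat-matrix leverages. Components are
extreme contiguous-cluster integrals of the deconvolved traces (largest
below-zero cluster after disappearance = dip; largest above-zero cluster
after reappearance = overshoot; %·s), estimated without selection bias by a
30-fold split-half procedure. Electrode-level gap-vs-blink tests use
stratified permutations with p = (b+1)/(m+1); the distribution of
significant electrodes across ROIs is tested with a randomization χ² test of
independence.

## Worked example

Simulate one full session (32 ten-trial blocks of 1 s images, gaps at
350/550/750 ms in 60% of gap-block trials, voluntary and spontaneous
blinks) for a face-selective high-level electrode, deconvolve, and test:

```r
library(hfbdeconv)

cfg   <- sim_config(seed = 42)                       # the standard task
sch   <- generate_schedule(cfg)
truth <- default_ground_truth(c("V1", "FC"), rate = 250, seed = 42)
hfb   <- generate_hfb_session(cfg, truth, sch)
hfb
#> <hfb_timecourse> 2 channels x 104750 samples @ 250 Hz, 0 masked

y <- hfb$values[2, ]                                 # the FC electrode
fit_off <- fir_deconv(build_design_matrix(
  predictor_sets(sch, lock = "offset", split_by_category = FALSE),
  n_time = length(y), rate = 250), y)
fit_on <- fir_deconv(build_design_matrix(
  predictor_sets(sch, lock = "onset", split_by_category = FALSE),
  n_time = length(y), rate = 250), y)
summary(fit_off)
#>           set n_lags        peak peak_lag_ms     trough trough_lag_ms
#> 1         gap    187  2.07804250         182 -0.7719850           314
#> 2 spontaneous    187 -0.02763224         494 -1.9130504           -46
#> 3    stimulus    375 11.07248858         148  0.4370717             0
#> 4   voluntary    187  0.01545359        -250 -1.1375399           -22
```

The reappearance-locked gap trace peaks at +2.1% around 180 ms — the
overshoot — while both blink traces stay near zero, as expected for a
high-level site. Quantify the components and remove selection bias:

```r
quantify_components(fit_on, fit_off)
#>           set component    integral cluster_start_ms cluster_end_ms method
#> 1         gap       dip -0.09230644                2            186 plugin
#> 2         gap overshoot  0.23293013               62            266 plugin
#> 3 spontaneous       dip -0.54419420                2            494 plugin
#> 4 spontaneous overshoot  0.00000000               NA             NA plugin
#> 5   voluntary       dip -0.26581720                2            446 plugin
#> 6   voluntary overshoot  0.00000000               NA             NA plugin

split_half_estimate(y, sch, 250, component = "overshoot",
                    n_splits = 10, seed = 1)
#>           set component    integral     method n_splits
#> 1         gap overshoot  0.22364430 split_half       10
#> 2 spontaneous overshoot -0.02608167 split_half       10
#> 3   voluntary overshoot -0.03261919 split_half       10
```

The gap overshoot integral (~0.22 %·s) survives the split-half correction;
the blink overshoots collapse to zero. The electrode-level permutation test
confirms the gap–blink difference:

```r
permutation_test(y, sch, 250, component = "overshoot",
                 blink_type = "spontaneous", m = 199, seed = 1)[,
  c("component", "blink_type", "observed", "p_raw", "p_two_tailed")]
#>   component  blink_type  observed p_raw p_two_tailed
#> 1 overshoot spontaneous 0.2904968 0.005         0.01
```

`run_pipeline(pipeline_config(...))` chains all stages — simulation, HFB
preprocessing, blink detection, responsiveness screening, deconvolution,
component estimation, permutation and ROI inference — into one reproducible,
seeded run and returns the report bundle (grand-average traces per ROI,
component summaries, significance tables).

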