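---
title: "Methods: LN analysis of nonlinear spatial integration in bipolar cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LN analysis of nonlinear spatial integration in bipolar cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(bipolarLN)
```

## Scientific background

Retinal bipolar cells relay photoreceptor signals to ganglion cells through
graded membrane potentials. The classical view holds that a bipolar cell
pools its photoreceptor inputs linearly over its receptive field (RF)
center, so that simultaneous opposite contrasts inside the center cancel.
Intracellular recordings contradict this for many cells: a contrast-reversing
spot split into opposing halves evokes depolarizations at *both* reversals
("frequency doubling"), the signature of rectification acting *before*
spatial summation. This package implements the full quantitative tool chain
for that analysis — stimulus synthesis, a generative subunit-model
simulator, trace conditioning, linear-nonlinear (LN) model estimation,
scalar nonlinearity indices, the split-spot subunit prediction, and
current-injection analyses — so that every statistic can be exercised
end-to-end on synthetic recordings with known ground truth.

## The generative cell model

`subunit_cell()` builds the simulated cell; `simulate_voltage()` runs it at
1 kHz:

1. the stimulus (a `frame_sequence` in Weber contrast) is frame-hold
   upsampled to 1 ms resolution;
2. each subunit on a square grid (spacing 15 µm, photoreceptor-like tiling)
   averages the pixels inside its catchment square;
3. the local signal is convolved with a biphasic temporal kernel
   (sign-flipped for OFF cells) normalized so that a full-contrast preferred
   step peaks at 1;
4. a static local nonlinearity is applied *per subunit* — `linear`,
   `threshold_linear(θ, slope)` or `saturating` — before pooling; this
   ordering is the scientific point of the model: rectification before
   summation produces frequency doubling, rectification after summation
   does not;
5. subunit outputs are pooled with Gaussian weights (σ_center, default
   35 µm), optionally minus a wider suppressive surround
   (k_surr · surround pool, σ_surround ≥ σ_center);
6. the pooled drive enters the soma as a conductance-like light input:
   the voltage deflection is scaled by the driving-force ratio
   (E_rev − V_base)/(E_rev − V_rest), with E_rev = 0 mV for the
   nonselective cation input and V_base = V_rest + I·R_in under current
   injection. This deliberately replaces a full membrane ODE: it is exactly
   what the reversal-potential extrapolation analysis assumes, and it makes
   the split-spot amplitude an affine function of the baseline potential
   whose zero crossing is E_rev;
7. an optional saturating soma output function (`tanh`, used only as a
   negative control), then additive Gaussian noise (sd 0.2 mV per 1 ms
   sample) and a slow baseline drift (low-pass filtered Gaussian process,
   cutoff ≈ 1/timescale with a 20 s timescale, amplitude 0.5 mV) complete
   the trace.

### Why these defaults

* **Kernel shape.** The temporal kernel has two gamma-like lobes; the
  second, opposite-sign lobe is scaled by `biphasic_ratio`. The default
  0.55 gives a near-zero step-response plateau, i.e. a *transient* cell
  (sustained–transient index ≈ 0.07). This matches the cells that show
  nonlinear spatial integration, which are the transient ones; a sustained
  kernel would make the uniform-spot fundamental dominate the spatial
  nonlinearity index for purely arithmetic reasons. The population
  generator draws the ratio from [0.4, 0.6] and the peak latency from
  [40, 80] ms.
* **Subunit threshold θ** is expressed in the units of the filtered local
  contrast signal (a preferred full-contrast step peaks at +1). θ = 0 is
  half-wave rectification; θ = −2 is effectively affine over the
  stimulus-driven range, i.e. linear spatial integration. The population
  default θ ~ U(−2, 0) spans the observed continuum from linear to
  strongly rectifying cells.
* **Geometry.** σ_center defaults to 35 µm (RF width 3σ ≈ 105 µm, inside
  the 50–120 µm range typical of salamander bipolar cells); subunit
  spacing 15 µm follows photoreceptor dimensions. Stimulus pixels are
  2.5 µm at the photoreceptor layer; checkerboard noise uses 30 µm squares
  updated at 30 Hz; full-field Gaussian noise has contrast sd 0.3 at
  30 Hz; the naturalistic surrogate movie runs at 25 Hz with pixel sd
  0.45.
* **Membrane parameters.** V_rest = −45 mV, R_in = 183 MΩ, E_rev = 0 mV
  (nonselective cation input); g_gain = 5 mV scales a full preferred
  contrast step in the RF center to a ≈ 4–5 mV deflection, typical for
  these recordings.

### What the generator does and does not emulate

It reproduces the statistical structure the analyses rely on: graded
responses with additive noise and slow drift, local rectification before
Gaussian pooling, conductance-type driving-force scaling, and deterministic
seeding. It does **not** model spiking, amacrine feedback, adaptation,
photoreceptor dynamics beyond the linear kernel, or dendritic cable
effects. Passing tests therefore show that the *analysis chain* recovers
the properties of this model class correctly — not that real bipolar cells
obey the model.

## Trace conditioning

Raw 20 kHz traces are conditioned by a centered 80-sample running median
followed by stride-20 decimation (`condition_raw_trace()`; edge windows
shrink, and only the retained samples' medians are computed). Slow drift is
removed with a zero-phase 2nd-order Butterworth high-pass at 0.1 Hz
(`detrend_highpass()`); the forward–backward application avoids latency
distortion of onset measurements, which a causal filter would bias.
Responses are binned at the stimulus frame resolution by averaging the
membrane potential per frame interval. Epoch averages subtract the mean of
the 200 ms preceding stimulus onset per trial. Cycle averages of reversing
stimuli drop the first cycle (onset artifact) and remove the mean.

## LN-model estimation

`ln_fit()` implements the estimation sequence for graded potentials:

* **Response-weighted average** (`response_weighted_average()`): for each
  lag in [0, 2 s), the stimulus is weighted by the binned voltage —
  the graded-response analog of the spike-triggered average. The
  normalization divides by the number of time bins; after detrending the
  mean response is ~0, so a mean-weight denominator would be degenerate,
  and any positive scale is absorbed by the unit-norm filter components
  anyway.
* **Space–time factorization** (`factorize_strf()`): a 720 µm window is
  cropped around the peak-magnitude pixel (clipped and shifted at array
  edges) and the highest-ranked spatial and temporal components extracted
  by SVD. After a 2-D Gaussian is fitted to the spatial component, pixels
  outside its 3σ contour are zeroed and the factorization repeated. Both
  components carry unit Euclidean norm. SVD signs are arbitrary; the
  convention fixes the spatial map positive at the RF center so the
  temporal kernel carries the cell's polarity and a positive generator
  signal means preferred contrast — which the output-nonlinearity index
  requires.
* **Gaussian RF** (`fit_gaussian_rf()`): least-squares elliptical Gaussian
  (BFGS from moment-based starts); RF diameter = diameter of the circle
  with the area of the 1.5σ ellipse. Noisy RFs are flagged when the mean
  map value inside 3σ falls below 3× the noise level estimated from lags
  2–4 s.
* **Output function** (`estimate_output_function()`): the generator signal
  (spatial projection, then causal temporal convolution; the first 2 s are
  invalid) is split into 40 equal-occupancy bins; generator and voltage
  are averaged per bin. Prediction interpolates linearly through the bin
  means and extrapolates with the outermost segment slopes.
* **Cross-validation** (`crossvalidate_ln()`): either frozen-noise repeats
  (fit on non-repeated frames, score the trial-averaged frozen response;
  predictions are averaged over insertions since each insertion carries
  its own stimulus history) or random held-out segments with per-segment
  refits. Per-segment refits reuse the full-data 3σ contour mask — the
  mask depends only weakly on any single 300-frame segment, and refitting
  the Gaussian hundreds of times is slow and numerically fragile.
  Explained variance is the squared Pearson correlation; a constant
  prediction yields `NA`, not 0.

Space–time separability is assumed throughout, as in the source analyses;
the full-rank RWA is retained in the fitted object for diagnostics.

## Indices

All formulas operate on baselined, trial-averaged responses:

* `hyperpolarization_index()`: (V_dep + V_hyp)/(|V_dep| + |V_hyp|).
* `output_nonlinearity_index()`: slopes of straight lines fitted to the
  positive- and negative-generator halves of the output function,
  (S_pos − S_neg)/(|S_pos| + |S_neg|).
* `spatial_nonlinearity_index()`: Fourier power of the 1 s cycle average,
  (P_pattern(2 Hz) + P_pattern(4 Hz))/P_uniform(1 Hz); "power" is the
  squared DFT coefficient magnitude — any consistent normalization cancels
  in the ratio. The maximum over halves/quarters/25 µm checkerboard
  summarizes the cell. When the tested uniform diameters miss the pattern
  diameter, `interpolate_uniform_traces()` interpolates the two nearest
  uniform traces first.
* `grating_nonlinearity_index()`: mean(P2 + P4) over phases divided by the
  max P1 over phases, maximized over spatial periods.
* `sustained_transient_index()`: mean of the last 50 ms of the spot
  presentation over the peak.
* `response_latency()`: first crossing of 3× the baseline SD, and the time
  of the maximum.
* `fit_dog_profile()`: difference-of-Gaussians area function fitted to
  peak response vs spot size with k ≥ 0 and σ_surround ≥ σ_center
  (enforced by parametrizing σ_surround = σ_center + δ, δ ≥ 0 — the
  source description states no constraints, but unconstrained fits can
  invert center and surround); the local spot is the tested diameter
  closest to 3σ_center, falling back to the white-noise RF diameter when
  the fitted width exceeds 250 µm.
* `predict_patterned_from_uniform()` / `prediction_accuracy()`: the
  split-spot prediction is 0.5 × (first + second 500 ms half) of the
  uniform cycle average, concatenated twice; halves are aligned by
  stimulus phase, not latency, because the reversing patterned spot incurs
  the same delay. Accuracy normalizes the residual by the variance of the
  uniform response, so spatially linear cells (near-zero patterned
  response, near-zero prediction) score near 1 rather than 0/0.

## Current-injection analyses

`input_resistance()` is the slope of the (electrode-corrected) I–V line.
`current_injection_experiment()` simulates the split-spot protocol
(current from 1 s before a 0.5 s flash until 150 ms after offset; traces
smoothed with a Gaussian moving average, SD 10 ms, 50 ms window; unstable
current levels excluded by a baseline-SD threshold) and
`reversal_potential()` extrapolates the zero crossing of amplitude vs
baseline. The response amplitude is the *signed* deflection from baseline
with the largest magnitude: beyond E_rev the light response reverses sign,
and clipping the amplitude at zero would kink the line and bias the
intercept (by ≈ +13 mV in a noiseless check at these parameters).

## Numerical choices and degenerate inputs

* Pixel membership: a pixel belongs to a spot when its center lies inside
  the disk; patterned subfields are balanced to within one subfield's
  pixel count.
* Stimulus randomness is counter-based (a 32-bit hash of seed, frame and
  square index), so frozen-segment insertion never desynchronizes the
  fresh-noise stream and every frame is reproducible in isolation.
* Equal-occupancy binning needs ≥ 10 samples per bin (≥ 400 valid frames
  for 40 bins); fewer raise an error.
* Degenerate cases return `NA` with flags rather than silent defaults:
  both HPi extrema zero, one-sided output functions, uniform-spot power
  below the noise floor, non-negative amplitude-vs-baseline slopes,
  non-converged Gaussian or DoG fits.
* Sub-bin peak latency uses the quadratic through the extremum and its two
  neighbors — exact for a sampled parabola; boundary extrema are flagged.

## Problem sizes

The test suite and the acceptance script use sizes chosen to keep the full
run on a single CPU comfortable while leaving estimation noise well below
the tested tolerances: 20 minutes of white noise (36 000 frames at 30 Hz)
for the two-cell linear/rectified comparison, 10 minutes per cell for the
30-cell population recovery, 4 s reversing-spot batteries with 3 trials,
and 20 replicate current-injection experiments with 3 trials per current
level. These are stated as the package's own defaults for synthetic
studies; nothing in the methods depends on them.

## Known limitations

* The analysis targets graded potentials; no spike handling beyond the
  thin rate proxy used for the grating spatial-scale fit.
* The LN implementation is the plain response-weighted average — no
  regularized or whitened variants, which correlated stimuli would
  require; accordingly movie responses reuse white-noise filters.
* The naturalistic surrogate reproduces 1/f spatial statistics and
  temporal low-pass correlation only; it contains no objects, motion
  streaks or luminance adaptation, so movie analyses here probe the
  transfer of the LN machinery, not ecological validity.
* HDF5-based persistence of recordings is not provided; objects are plain
  R lists and can be saved with `saveRDS()`, and index tables are written
  as CSV.
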