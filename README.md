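# bipolarLN

Analysis of nonlinear spatial integration in retinal bipolar cells from
intracellular membrane-potential recordings — and a generative subunit-model
simulator to exercise every analysis on synthetic data with known ground
truth.

Bipolar cells are classically assumed to pool photoreceptor input linearly
over their receptive-field (RF) center, so that opposing contrasts inside
the center cancel. Contrast-reversing "split spots" test this directly: a
linearly integrating cell stays silent, whereas local rectification *before*
spatial summation produces depolarizations at **both** reversals — frequency
doubling at twice the reversal rate. This package implements the complete
tool chain used to quantify that phenomenon:

* **Stimuli** (`render_spot`, `render_grating`, `render_checkerboard_noise`,
  `render_fullfield_noise`, `render_movie_surrogate`): spots (uniform,
  halves, quarters, 25/10 µm checkerboards), reversing sine and square-wave
  gratings, binary checkerboard and Gaussian full-field white noise with
  frozen test segments, and a seeded 1/f naturalistic movie surrogate — all
  in Weber contrast on a micrometer pixel grid.
* **Simulator** (`subunit_cell`, `simulate_voltage`): subunit grid →
  biphasic temporal filtering → static local nonlinearity → Gaussian
  center/surround pooling → conductance-like light input with driving-force
  scaling (reversal potential E_rev) → noise and slow drift, at 1 kHz.
* **LN model** (`ln_fit`, an S3 model with `print`/`summary`/`coef`/
  `predict`/`plot`/`residuals` methods): response-weighted average over a
  2 s window, SVD space–time factorization in a 720 µm crop, 2-D Gaussian
  RF fit with 3σ masking, 40-bin equal-occupancy output function,
  linear inter-/extrapolating prediction, and cross-validated explained
  variance (frozen-noise repeats or held-out segments);
  `movie_nonlinearity` transfers white-noise filters to movie responses.
* **Indices** (`hyperpolarization_index`, `output_nonlinearity_index`,
  `spatial_nonlinearity_index`, `grating_nonlinearity_index`,
  `sustained_transient_index`, `response_latency`, `fit_dog_profile`,
  `oscillation_frequency`, `grating_spatial_scale`, ...):

  * HPi = (V_dep + V_hyp) / (|V_dep| + |V_hyp|)
  * ONi = (S_pos − S_neg) / (|S_pos| + |S_neg|)
  * SNi = (P_pattern(2 Hz) + P_pattern(4 Hz)) / P_uniform(1 Hz)
  * STi = V_steady-state / V_peak
  * V(r) = k_c (1 − e^(−r²/2σ_c²)) − k_s (1 − e^(−r²/2σ_s²)) (spot-size fit)

* **Split-spot prediction** (`predict_patterned_from_uniform`,
  `prediction_accuracy`): if the only nonlinearity is local, the patterned
  response equals half the black- plus half the white-phase uniform
  response; accuracy = 1 − Σ(V_pattern − V_pred)² / Σ(V_uniform − V̄)².
* **Physiology** (`input_resistance`, `reversal_potential`,
  `current_injection_experiment`): I–V slope and extrapolation of the
  light input's reversal potential from amplitude vs baseline potential
  under current injection.
* **Pipeline** (`run_experiment`, `population_stats`): seeded end-to-end
  runs over cell populations producing one tidy index row per cell.

## Worked example

A rectifying-subunit model cell (threshold θ = 0, i.e. half-wave
rectification of each subunit's filtered contrast signal) run through the
patterned-spot battery, the split-spot prediction, and the white-noise LN
analysis:

```r
library(bipolarLN)

cell <- subunit_cell(nonlinearity = list(type = "threshold_linear",
                                         threshold = 0))
cell
#> <subunit_cell> OFF, subunits threshold-linear (theta = 0.00), spacing 15 um
#>   pooling sigma 35 um; V_rest -45 mV, E_rev 0 mV, R_in 183 MOhm

bat <- measure_spot_battery(cell, diameter_um = 100, seed = 1)
round(bat$sni, 3)
#>   halves quarters  check25
#>    0.850    0.507    0.253

pred <- measure_split_spot_prediction(cell, 100, seed = 1)
round(pred$accuracy, 3)
#> [1] 0.977

ln <- measure_ln_battery(cell, "checkerboard", duration_s = 300, seed = 1)
ln$model
#> <ln_model> 10 x 10 px spatial x temporal filter, 60 lags at 30 Hz
#>   polarity OFF, time-to-peak 39.4 ms, biphasic index 0.62
#>   RF diameter (1.5 sigma) 107.5 um
#>   output function: 40 bins; training R^2 = 0.793
round(c(r2 = ln$r2, oni = ln$oni), 3)
#>    r2   oni
#> 0.815 0.193
```

Reading the numbers: the spatial nonlinearity index of 0.85 for the split
spot signals strong frequency doubling (a linearly pooling cell gives
≈ 0); it falls toward zero for finer patterns (0.25 at 25 µm squares),
locating the spatial scale of the nonlinearity between ~30 µm and the RF
diameter. The split-spot prediction accuracy of 0.98 says the patterned
response is explained by the uniform-spot responses alone — the signature
of a purely local nonlinearity with linear summation. The LN model fitted
to 5 minutes of 30 µm checkerboard noise recovers an OFF-polarity biphasic
filter and a 107 µm RF (ground truth 3σ = 105 µm); its held-out explained
variance of 0.82 is depressed relative to a spatially linear cell (> 0.95
under the same protocol) because the LN model cannot represent
rectification that precedes spatial pooling.

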