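# Shared fixtures: deterministic cells and small stimuli built in code.

noiseless <- function(...) {
  subunit_cell(..., noise_sd_mv = 0,
               drift = list(amplitude_mv = 0, timescale_s = 20))
}

linear_cell <- function(...) noiseless(nonlinearity = list(type = "linear"), ...)

rectified_cell <- function(theta = 0, ...) {
  noiseless(nonlinearity = list(type = "threshold_linear", threshold = theta),
            ...)
}

# small canvas covering the default cell's pooling extent
default_canvas <- function(width_um = 240, pixel_size_um = 2.5) {
  stim_canvas(width_um, pixel_size_um = pixel_size_um)
}

reversing_spot <- function(pattern, diameter_um = 100, duration_s = 4,
                           canvas = default_canvas(), contrast = -1,
                           frame_rate_hz = 60, ...) {
  render_spot(spot_spec(diameter_um = diameter_um, pattern = pattern,
                        contrast = contrast, mode = "reversing",
                        stim_duration_s = duration_s,
                        background_duration_s = 0.2,
                        lead_background_s = 1, ...),
              canvas, frame_rate_hz)
}

# seconds of binary checkerboard noise sized for the default cell
small_noise <- function(duration_s, seed = 1, ...) {
  render_checkerboard_noise(noise_spec(duration_s = duration_s,
                                       extent_um = 240, seed = seed, ...))
}
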