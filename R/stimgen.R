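# Stimulus rendering: spots, gratings, white noise, naturalistic surrogate.
# All stimuli are expressed in Weber contrast (background = 0, binary = +-1)
# on a pixel grid in micrometers at the photoreceptor layer.

#' Pixel-grid stimulus movie in Weber contrast
#'
#' The common container exchanged between stimulus rendering, the voltage
#' simulator and LN-model estimation.  `frames` holds one matrix per stimulus
#' frame (rows = y, columns = x); the world coordinate of the pixel-(1,1)
#' corner is `origin_um`, and pixel centers sit at offsets of half a pixel.
#'
#' @param frames numeric array `T x H x W` of Weber contrast values.
#' @param pixel_size_um micrometers per pixel (square pixels).
#' @param frame_rate_hz stimulus update rate in Hz.
#' @param origin_um length-2 numeric, world (x, y) of the grid corner.
#' @param background_value contrast of the background (0).
#' @return an object of class `"frame_sequence"`.
#' @export
frame_sequence <- function(frames, pixel_size_um, frame_rate_hz,
                           origin_um = c(0, 0), background_value = 0) {
  frames <- unclass(frames)
  if (length(dim(frames)) != 3)
    stop("`frames` must be a T x H x W array")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be positive")
  if (frame_rate_hz <= 0) stop("`frame_rate_hz` must be positive")
  structure(
    list(frames = frames, pixel_size_um = pixel_size_um,
         frame_rate_hz = frame_rate_hz, origin_um = as.numeric(origin_um),
         background_value = background_value),
    class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_sequence> %d frames of %d x %d px (%.1f um/px, %.4g Hz)\n",
    d[1], d[2], d[3], x$pixel_size_um, x$frame_rate_hz))
  cat(sprintf("  extent: %.1f x %.1f um, origin (%.1f, %.1f) um\n",
              d[3] * x$pixel_size_um, d[2] * x$pixel_size_um,
              x$origin_um[1], x$origin_um[2]))
  invisible(x)
}

#' @export
dim.frame_sequence <- function(x) dim(x$frames)

n_frames <- function(fs) dim(fs$frames)[1]

# World coordinates of pixel centers, as vectors over columns (x) / rows (y).
pixel_centers <- function(fs_or_geom) {
  g <- fs_or_geom
  d <- if (inherits(g, "frame_sequence")) dim(g$frames)[2:3] else
    c(g$n_rows, g$n_cols)
  list(x = g$origin_um[1] + (seq_len(d[2]) - 0.5) * g$pixel_size_um,
       y = g$origin_um[2] + (seq_len(d[1]) - 0.5) * g$pixel_size_um)
}

#' Define a stimulus canvas
#'
#' @param width_um,height_um canvas extent in micrometers.
#' @param pixel_size_um micrometers per pixel (2.5 at the photoreceptor
#'   layer for the standard display configuration).
#' @param center_um world coordinate of the canvas center.
#' @return geometry list used by the renderers.
#' @export
stim_canvas <- function(width_um, height_um = width_um, pixel_size_um = 2.5,
                        center_um = c(0, 0)) {
  n_cols <- round(width_um / pixel_size_um)
  n_rows <- round(height_um / pixel_size_um)
  if (n_cols < 1 || n_rows < 1) stop("canvas smaller than one pixel")
  list(n_rows = n_rows, n_cols = n_cols, pixel_size_um = pixel_size_um,
       origin_um = c(center_um[1] - n_cols * pixel_size_um / 2,
                     center_um[2] - n_rows * pixel_size_um / 2))
}

#' Specification of a (patterned) spot stimulus
#'
#' @param center_um world (x, y) of the spot center.
#' @param diameter_um spot diameter.
#' @param pattern `"uniform"`, `"halves"`, `"quarters"`, `"check25"` or
#'   `"check10"` (checkerboard subfields of 25 or 10 um).
#' @param contrast Weber contrast of the (first phase of the) pattern.
#' @param mode `"flash"` (hold for `stim_duration_s`, then background) or
#'   `"reversing"` (full pattern sign alternates at `reversal_hz`).
#' @param reversal_hz contrast-reversal frequency (default 1 Hz).
#' @param stim_duration_s,background_duration_s stimulus / trailing
#'   background durations in seconds.
#' @param lead_background_s background duration preceding the stimulus,
#'   used for baseline measurement.
#' @param split_orientation_deg orientation of the halves/quarters split;
#'   0 = vertical split through the spot center.
#' @return a `spot_spec` list.
#' @export
spot_spec <- function(center_um = c(0, 0), diameter_um, pattern = "uniform",
                      contrast = -1, mode = "flash", reversal_hz = 1,
                      stim_duration_s = 0.5, background_duration_s = 1,
                      lead_background_s = 0, split_orientation_deg = 0) {
  pattern <- match.arg(pattern,
                       c("uniform", "halves", "quarters", "check25", "check10"))
  mode <- match.arg(mode, c("flash", "reversing"))
  if (diameter_um <= 0) stop("`diameter_um` must be positive")
  structure(list(center_um = center_um, diameter_um = diameter_um,
                 pattern = pattern, contrast = contrast, mode = mode,
                 reversal_hz = reversal_hz, stim_duration_s = stim_duration_s,
                 background_duration_s = background_duration_s,
                 lead_background_s = lead_background_s,
                 split_orientation_deg = split_orientation_deg),
            class = "spot_spec")
}

# Contrast pattern of a spot on a canvas as an H x W matrix (background 0).
spot_pattern_matrix <- function(spec, canvas) {
  pc <- pixel_centers(canvas)
  dx <- outer(rep(1, canvas$n_rows), pc$x - spec$center_um[1])
  dy <- outer(pc$y - spec$center_um[2], rep(1, canvas$n_cols))
  r <- spec$diameter_um / 2
  inside <- (dx^2 + dy^2) < r^2
  # rotated coordinates for the split orientation
  th <- spec$split_orientation_deg * pi / 180
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  sgn <- switch(
    spec$pattern,
    uniform = matrix(1, canvas$n_rows, canvas$n_cols),
    halves = ifelse(u >= 0, 1, -1),
    quarters = ifelse((u >= 0) == (v >= 0), 1, -1),
    check25 = (-1)^(floor(u / 25) + floor(v / 25)),
    check10 = (-1)^(floor(u / 10) + floor(v / 10)))
  m <- matrix(0, canvas$n_rows, canvas$n_cols)
  m[inside] <- (spec$contrast * sgn)[inside]
  m
}

#' Render a (patterned) spot stimulus
#'
#' Pixels belong to the spot if their center lies inside the disk; pixels
#' outside the disk stay at the background contrast of 0.  In `"reversing"`
#' mode the whole pattern alternates sign at `reversal_hz`; in `"flash"` mode
#' the pattern is held for `stim_duration_s` and followed by background.
#'
#' @param spec a [spot_spec()].
#' @param canvas a [stim_canvas()]; the spot must fit on it.
#' @param frame_rate_hz display frame rate.
#' @return a [frame_sequence()].
#' @export
render_spot <- function(spec, canvas, frame_rate_hz = 60) {
  half <- spec$diameter_um / 2
  over <- max(
    (spec$center_um[1] + half) - (canvas$origin_um[1] +
                                    canvas$n_cols * canvas$pixel_size_um),
    canvas$origin_um[1] - (spec$center_um[1] - half),
    (spec$center_um[2] + half) - (canvas$origin_um[2] +
                                    canvas$n_rows * canvas$pixel_size_um),
    canvas$origin_um[2] - (spec$center_um[2] - half))
  if (over > 0)
    stop(sprintf("spot exceeds canvas by %.1f um", over))
  pat <- spot_pattern_matrix(spec, canvas)
  n_lead <- round(spec$lead_background_s * frame_rate_hz)
  n_stim <- round(spec$stim_duration_s * frame_rate_hz)
  n_bg <- round(spec$background_duration_s * frame_rate_hz)
  t_stim <- (seq_len(n_stim) - 1) / frame_rate_hz
  gain <- if (spec$mode == "reversing") {
    ifelse(floor(t_stim * 2 * spec$reversal_hz) %% 2 == 0, 1, -1)
  } else rep(1, n_stim)
  gain <- c(rep(0, n_lead), gain, rep(0, n_bg))
  frames <- array(0, c(length(gain), canvas$n_rows, canvas$n_cols))
  for (f in which(gain != 0)) frames[f, , ] <- gain[f] * pat
  frame_sequence(frames, canvas$pixel_size_um, frame_rate_hz,
                 origin_um = canvas$origin_um)
}

#' Specification of a white-noise stimulus
#'
#' @param layout `"checkerboard"` (independent squares) or `"fullfield"`
#'   (one scalar per frame broadcast over space).
#' @param square_size_um side of a stimulus square (checkerboard).
#' @param update_rate_hz stimulus update rate.
#' @param distribution `"binary"` (+-1, 100% contrast) or `"gaussian"`.
#' @param sd standard deviation of the Gaussian distribution in Weber
#'   contrast (0.3, i.e. 30% contrast, for the full-field stimulus).
#' @param duration_s total stimulus duration (including frozen insertions).
#' @param frozen_length_frames,frozen_period_frames optional frozen test
#'   segment: a fixed `frozen_length_frames`-frame sequence is inserted after
#'   every `frozen_period_frames` frames of fresh noise and repeated verbatim
#'   at every insertion.
#' @param extent_um spatial extent of the checkerboard (width = height).
#' @param center_um world coordinate of the stimulus center.
#' @param seed integer seed for the counter-based generator.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(layout = "checkerboard", square_size_um = 30,
                       update_rate_hz = 30, distribution = "binary",
                       sd = 0.3, duration_s, frozen_length_frames = NULL,
                       frozen_period_frames = NULL, extent_um = 240,
                       center_um = c(0, 0), seed = 1) {
  layout <- match.arg(layout, c("checkerboard", "fullfield"))
  distribution <- match.arg(distribution, c("binary", "gaussian"))
  if (layout == "checkerboard" &&
      abs(square_size_um / 2.5 - round(square_size_um / 2.5)) > 1e-9)
    stop("`square_size_um` must be a multiple of the 2.5 um display pixel")
  if (!is.null(frozen_length_frames) && is.null(frozen_period_frames))
    stop("`frozen_period_frames` required with a frozen segment")
  structure(list(layout = layout, square_size_um = square_size_um,
                 update_rate_hz = update_rate_hz, distribution = distribution,
                 sd = sd, duration_s = duration_s,
                 frozen_length_frames = frozen_length_frames,
                 frozen_period_frames = frozen_period_frames,
                 extent_um = extent_um, center_um = center_um, seed = seed),
            class = "noise_spec")
}

# frame indices of frozen insertions for T frames; returns logical vector
# plus, for frozen frames, the index (1..L) within the frozen block.
frozen_schedule <- function(n_frames, len, period) {
  frozen <- logical(n_frames)
  within <- integer(n_frames)
  if (is.null(len)) return(list(frozen = frozen, within = within))
  f <- 1; fresh <- 0
  while (f <= n_frames) {
    if (fresh == period) {
      take <- min(len, n_frames - f + 1)
      frozen[f:(f + take - 1)] <- TRUE
      within[f:(f + take - 1)] <- seq_len(take)
      f <- f + take; fresh <- 0
    } else {
      f <- f + 1; fresh <- fresh + 1
    }
  }
  list(frozen = frozen, within = within)
}

#' Render binary checkerboard white noise
#'
#' Each square is updated independently to +1 or -1 (100% contrast) at the
#' update rate.  Samples come from a counter-based generator keyed by
#' `(seed, frame, square)`, so identical seeds give bit-identical movies and
#' the optional frozen segment is excluded from the fresh-noise stream.
#'
#' @param spec a [noise_spec()] with `layout = "checkerboard"` and
#'   `distribution = "binary"`.
#' @return a [frame_sequence()] whose pixel size equals the square size.
#' @export
render_checkerboard_noise <- function(spec) {
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$layout != "checkerboard" || spec$distribution != "binary")
    stop("spec must describe binary checkerboard noise")
  n_sq <- round(spec$extent_um / spec$square_size_um)
  if (abs(n_sq * spec$square_size_um - spec$extent_um) > 1e-9)
    stop("`extent_um` must be a multiple of `square_size_um`")
  n_f <- round(spec$duration_s * spec$update_rate_hz)
  sched <- frozen_schedule(n_f, spec$frozen_length_frames,
                           spec$frozen_period_frames)
  # fresh frames consume counters 1,2,...; frozen frames use a separate
  # stream keyed by position within the frozen block
  fresh_counter <- cumsum(!sched$frozen)
  frame_key <- ifelse(sched$frozen, sched$within, fresh_counter)
  stream <- ifelse(sched$frozen, 1, 0)
  n_units <- n_sq * n_sq
  u <- counter_uniform(spec$seed,
                       frame = rep(frame_key, each = n_units),
                       unit = rep.int(seq_len(n_units), n_f),
                       stream = rep(stream, each = n_units))
  vals <- ifelse(u < 0.5, -1, 1)
  frames <- aperm(array(vals, c(n_sq, n_sq, n_f)), c(3, 1, 2))
  frame_sequence(frames, spec$square_size_um, spec$update_rate_hz,
                 origin_um = c(spec$center_um[1] - spec$extent_um / 2,
                               spec$center_um[2] - spec$extent_um / 2))
}

#' Render full-field white noise
#'
#' One contrast value per frame, drawn from a Gaussian distribution (in
#' Weber contrast) or binary +-1, broadcast over space.  Stored as a single
#' pixel spanning `extent_um` since the stimulus has no spatial structure.
#'
#' @param spec a [noise_spec()] with `layout = "fullfield"`.
#' @return a [frame_sequence()] with one pixel per frame.
#' @export
render_fullfield_noise <- function(spec) {
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$layout != "fullfield") stop("spec must describe full-field noise")
  n_f <- round(spec$duration_s * spec$update_rate_hz)
  sched <- frozen_schedule(n_f, spec$frozen_length_frames,
                           spec$frozen_period_frames)
  fresh_counter <- cumsum(!sched$frozen)
  frame_key <- ifelse(sched$frozen, sched$within, fresh_counter)
  stream <- ifelse(sched$frozen, 1, 0)
  vals <- if (spec$distribution == "gaussian") {
    spec$sd * counter_normal(spec$seed, frame_key, unit = 0, stream = stream)
  } else {
    ifelse(counter_uniform(spec$seed, frame_key, 0, stream) < 0.5, -1, 1)
  }
  frames <- array(vals, c(n_f, 1, 1))
  frame_sequence(frames, spec$extent_um, spec$update_rate_hz,
                 origin_um = c(spec$center_um[1] - spec$extent_um / 2,
                               spec$center_um[2] - spec$extent_um / 2))
}

#' Specification of a contrast-reversing grating
#'
#' @param kind `"fullfield_sine"` or `"squarewave_bars"`.
#' @param spatial_period_um spatial period of the sine grating.
#' @param n_phases number of equally spaced spatial phases (8).
#' @param reversal_hz contrast-reversal frequency (1 Hz).
#' @param duration_s stimulus duration.
#' @param amplitude contrast amplitude of the grating.
#' @param bar_width_um bar width for square-wave gratings.
#' @return a `grating_spec` list.
#' @export
grating_spec <- function(kind = "fullfield_sine", spatial_period_um = 80,
                         n_phases = 8, reversal_hz = 1, duration_s = 8,
                         amplitude = 1, bar_width_um = NULL) {
  kind <- match.arg(kind, c("fullfield_sine", "squarewave_bars"))
  if (n_phases < 1) stop("`n_phases` must be >= 1")
  if (kind == "squarewave_bars" && is.null(bar_width_um))
    stop("`bar_width_um` required for square-wave gratings")
  structure(list(kind = kind, spatial_period_um = spatial_period_um,
                 n_phases = n_phases, reversal_hz = reversal_hz,
                 duration_s = duration_s, amplitude = amplitude,
                 bar_width_um = bar_width_um),
            class = "grating_spec")
}

#' Render contrast-reversing gratings at all spatial phases
#'
#' Sine gratings vary along x with the requested spatial period and reverse
#' contrast at `reversal_hz`; the `n_phases` spatial phases are equally
#' spaced over one period.  Square-wave bar gratings (for the ganglion-cell
#' spatial-scale protocol) use `bar_width_um` (period = 2 bars).
#'
#' @param spec a [grating_spec()].
#' @param canvas a [stim_canvas()].
#' @param frame_rate_hz display frame rate.
#' @return a list of [frame_sequence()], one per spatial phase.
#' @export
render_grating <- function(spec, canvas, frame_rate_hz = 60) {
  period <- if (spec$kind == "fullfield_sine") spec$spatial_period_um
    else 2 * spec$bar_width_um
  if (period < 2 * canvas$pixel_size_um)
    stop("spatial period below twice the pixel size")
  pc <- pixel_centers(canvas)
  n_f <- round(spec$duration_s * frame_rate_hz)
  t <- (seq_len(n_f) - 1) / frame_rate_hz
  gain <- ifelse(floor(t * 2 * spec$reversal_hz) %% 2 == 0, 1, -1)
  lapply(seq_len(spec$n_phases) - 1, function(k) {
    shift <- k * period / spec$n_phases
    prof <- if (spec$kind == "fullfield_sine") {
      spec$amplitude * sin(2 * pi * (pc$x - shift) / period)
    } else {
      spec$amplitude * ifelse(floor((pc$x - shift) / spec$bar_width_um)
                              %% 2 == 0, 1, -1)
    }
    base <- matrix(prof, canvas$n_rows, canvas$n_cols, byrow = TRUE)
    frames <- array(0, c(n_f, canvas$n_rows, canvas$n_cols))
    for (f in seq_len(n_f)) frames[f, , ] <- gain[f] * base
    frame_sequence(frames, canvas$pixel_size_um, frame_rate_hz,
                   origin_um = canvas$origin_um)
  })
}

#' Render a naturalistic movie surrogate
#'
#' A seeded, spatiotemporally correlated contrast movie standing in for
#' head-camera footage of outdoor scenes: spatial 1/f-type amplitude
#' spectrum, temporally low-pass (AR(1) frame-to-frame correlation), scaled
#' to mean 0 and a target pixel standard deviation of 0.45 Weber contrast.
#' This surrogate reproduces the second-order statistics the analyses rely
#' on, not object content.
#'
#' @param duration_s movie duration.
#' @param frame_rate_hz frame rate (25 Hz).
#' @param extent_um spatial extent (width = height).
#' @param pixel_size_um pixel size; 22.5 um matches the white-noise grid
#'   used for receptive-field estimation of movie-stimulated cells.
#' @param target_sd target pixel standard deviation in Weber contrast.
#' @param temporal_corr AR(1) correlation between consecutive frames.
#' @param center_um world coordinate of the movie center.
#' @param seed integer seed.
#' @return a [frame_sequence()].
#' @export
render_movie_surrogate <- function(duration_s, frame_rate_hz = 25,
                                   extent_um = 240, pixel_size_um = 22.5,
                                   target_sd = 0.45, temporal_corr = 0.85,
                                   center_um = c(0, 0), seed = 1) {
  n_px <- round(extent_um / pixel_size_um)
  n_f <- round(duration_s * frame_rate_hz)
  # 1/f-type spatial filter in the frequency domain
  fx <- c(0:(n_px %/% 2), -((n_px - n_px %/% 2 - 1):1)) / n_px
  k <- sqrt(outer(fx^2, fx^2, "+"))
  amp <- 1 / (k + 1 / n_px)
  innov_field <- function(f) {
    z <- matrix(counter_normal(seed, f, seq_len(n_px * n_px)), n_px, n_px)
    Re(fft(fft(z) * amp, inverse = TRUE)) / (n_px * n_px)
  }
  frames <- array(0, c(n_f, n_px, n_px))
  state <- innov_field(0)
  rho <- temporal_corr
  for (f in seq_len(n_f)) {
    state <- rho * state + sqrt(1 - rho^2) * innov_field(f)
    frames[f, , ] <- state
  }
  frames <- frames - mean(frames)
  frames <- frames * (target_sd / stats::sd(as.vector(frames)))
  frame_sequence(frames, pixel_size_um, frame_rate_hz,
                 origin_um = c(center_um[1] - extent_um / 2,
                               center_um[2] - extent_um / 2))
}
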