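# Generative subunit-model simulator of bipolar-cell membrane potential.
#
# Architecture: the stimulus is averaged within small subunit catchments,
# temporally filtered by a biphasic kernel (sign-flipped for OFF cells),
# passed through a static local nonlinearity, and pooled with a Gaussian
# center (optionally minus a wider suppressive surround).  The pooled drive
# enters the soma as a conductance-like light input whose effect scales with
# the driving force (E_rev - V_base), is optionally passed through a soma
# output function, and is finally corrupted by per-sample Gaussian noise and
# slow baseline drift.  Simulation runs at 1 kHz.

SIM_RATE_HZ <- 1000

#' Uniform-rate membrane-potential trace
#'
#' @param samples_mv numeric vector of membrane potential in mV.
#' @param rate_hz sampling rate (1000 after conditioning/simulation).
#' @param t0_s time of the first sample.
#' @param trial_id optional trial identifier.
#' @return an object of class `"voltage_trace"`.
#' @export
voltage_trace <- function(samples_mv, rate_hz, t0_s = 0, trial_id = NA) {
  if (any(!is.finite(samples_mv))) stop("voltage samples must be finite")
  if (rate_hz <= 0) stop("`rate_hz` must be positive")
  structure(list(samples_mv = as.numeric(samples_mv), rate_hz = rate_hz,
                 t0_s = t0_s, trial_id = trial_id),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples at %g Hz (%.2f s), %.2f .. %.2f mV\n",
              length(x$samples_mv), x$rate_hz,
              length(x$samples_mv) / x$rate_hz,
              min(x$samples_mv), max(x$samples_mv)))
  invisible(x)
}

#' @export
length.voltage_trace <- function(x) length(x$samples_mv)

trace_times <- function(tr) tr$t0_s + (seq_along(tr$samples_mv) - 1) / tr$rate_hz

#' Parametric biphasic temporal kernel
#'
#' Two gamma-like lobes of opposite sign; the first peaks at
#' `peak_latency_ms`, the second (scaled by `biphasic_ratio`) at 1.8 times
#' that latency.  The kernel is normalized so that the peak response to a
#' unit contrast step equals one, which makes `g_gain_mv` of a cell the
#' approximate peak depolarization (in mV) to a full-contrast preferred
#' step in the receptive field center.
#'
#' @param peak_latency_ms latency of the first lobe's peak.
#' @param biphasic_ratio relative weight of the opposite-sign second lobe
#'   (0 = monophasic).
#' @param duration_ms kernel support (<= 2000).
#' @param rate_hz sampling rate of the kernel.
#' @return numeric vector of per-sample kernel weights.
#' @export
biphasic_kernel <- function(peak_latency_ms = 50, biphasic_ratio = 0.55,
                            duration_ms = 400, rate_hz = SIM_RATE_HZ) {
  stopifnot(duration_ms <= 2000, peak_latency_ms > 0, biphasic_ratio >= 0)
  t <- seq_len(round(duration_ms * rate_hz / 1000)) * 1000 / rate_hz
  lobe <- function(tp, n = 6) (t / tp)^n * exp(n * (1 - t / tp))
  k <- lobe(peak_latency_ms) - biphasic_ratio * lobe(1.8 * peak_latency_ms)
  k / max(abs(cumsum(k)))  # peak response to a unit contrast step = 1
}

#' Construct a generative subunit-model cell
#'
#' @param polarity `"ON"` or `"OFF"` (preferred contrast positive/negative).
#' @param center_um world (x, y) of the receptive-field center.
#' @param subunit_spacing_um spacing of the square subunit grid; the default
#'   15 um mirrors photoreceptor-scale tiling.
#' @param kernel list with `peak_latency_ms`, `biphasic_ratio`,
#'   `duration_ms` for [biphasic_kernel()].
#' @param nonlinearity list with `type` in `"linear"`,
#'   `"threshold_linear"` (`threshold`, `slope`) or `"saturating"`
#'   (`half_sat`, `max`); applied to each subunit's filtered signal before
#'   pooling.  `threshold` is in the same generator units as the filtered
#'   contrast signal (a full preferred contrast step peaks at +1).
#' @param pooling list with Gaussian `sigma_center_um` and optional
#'   suppressive surround `sigma_surround_um`, `k_surr` (weight >= 0).
#' @param soma `"identity"` or list `type = "saturating"` with `v_sat_mv`
#'   (tanh saturation applied to the light-evoked voltage).
#' @param noise_sd_mv per-sample Gaussian noise SD at 1 kHz.
#' @param drift list `amplitude_mv`, `timescale_s` of the slow baseline
#'   drift (low-pass filtered Gaussian process).
#' @param v_rest_mv resting potential.
#' @param e_rev_mv reversal potential of the light-driven (cation) input.
#' @param g_gain_mv light-drive gain: mV of depolarization per unit pooled
#'   drive at the resting driving force.
#' @param r_in_mohm input resistance in megaohms (baseline shift under
#'   current injection is `I_pA * R_in_MOhm / 1000` mV).
#' @return an object of class `"subunit_cell"`.
#' @export
subunit_cell <- function(polarity = c("OFF", "ON"), center_um = c(0, 0),
                         subunit_spacing_um = 15,
                         kernel = list(), nonlinearity = list(type = "linear"),
                         pooling = list(), soma = "identity",
                         noise_sd_mv = 0.2,
                         drift = list(amplitude_mv = 0.5, timescale_s = 20),
                         v_rest_mv = -45, e_rev_mv = 0, g_gain_mv = 5,
                         r_in_mohm = 183) {
  polarity <- match.arg(polarity)
  kernel <- utils::modifyList(
    list(peak_latency_ms = 50, biphasic_ratio = 0.55, duration_ms = 400),
    kernel)
  nonlinearity <- utils::modifyList(
    list(type = "linear", threshold = 0, slope = 1, half_sat = 0.5, max = 2),
    nonlinearity)
  nonlinearity$type <- match.arg(nonlinearity$type,
                                 c("linear", "threshold_linear", "saturating"))
  pooling <- utils::modifyList(
    list(sigma_center_um = 35, sigma_surround_um = NULL, k_surr = 0),
    pooling)
  if (pooling$k_surr > 0) {
    if (is.null(pooling$sigma_surround_um))
      stop("surround weight given without `sigma_surround_um`")
    if (pooling$sigma_surround_um < pooling$sigma_center_um)
      stop("`sigma_surround_um` must be >= `sigma_center_um`")
  }
  if (is.character(soma)) soma <- list(type = soma)
  soma <- utils::modifyList(list(type = "identity", v_sat_mv = 2), soma)
  soma$type <- match.arg(soma$type, c("identity", "saturating"))
  if (noise_sd_mv < 0) stop("`noise_sd_mv` must be >= 0")
  structure(list(polarity = polarity, center_um = center_um,
                 subunit_spacing_um = subunit_spacing_um, kernel = kernel,
                 nonlinearity = nonlinearity, pooling = pooling, soma = soma,
                 noise_sd_mv = noise_sd_mv, drift = drift,
                 v_rest_mv = v_rest_mv, e_rev_mv = e_rev_mv,
                 g_gain_mv = g_gain_mv, r_in_mohm = r_in_mohm),
            class = "subunit_cell")
}

#' @export
print.subunit_cell <- function(x, ...) {
  nl <- x$nonlinearity
  nl_txt <- switch(nl$type,
    linear = "linear",
    threshold_linear = sprintf("threshold-linear (theta = %.2f)", nl$threshold),
    saturating = sprintf("saturating (half-sat %.2f)", nl$half_sat))
  cat(sprintf("<subunit_cell> %s, subunits %s, spacing %g um\n",
              x$polarity, nl_txt, x$subunit_spacing_um))
  cat(sprintf("  pooling sigma %g um%s; V_rest %g mV, E_rev %g mV, R_in %g MOhm\n",
              x$pooling$sigma_center_um,
              if (x$pooling$k_surr > 0)
                sprintf(" (surround sigma %g, k %g)",
                        x$pooling$sigma_surround_um, x$pooling$k_surr) else "",
              x$v_rest_mv, x$e_rev_mv, x$r_in_mohm))
  invisible(x)
}

subunit_nl_fun <- function(nl) {
  switch(nl$type,
         linear = identity,
         threshold_linear = function(x) nl$slope * pmax(x - nl$threshold, 0),
         saturating = function(x) {
           xp <- pmax(x, 0); nl$max * xp / (nl$half_sat + xp)
         })
}

soma_fun <- function(soma) {
  if (soma$type == "identity") identity
  else function(x) soma$v_sat_mv * tanh(x / soma$v_sat_mv)
}

# Subunit grid geometry + pooling weights for a cell.
subunit_layout <- function(cell) {
  p <- cell$pooling
  sig_max <- max(p$sigma_center_um,
                 if (p$k_surr > 0) p$sigma_surround_um else 0)
  s <- cell$subunit_spacing_um
  half <- s * ceiling(3 * sig_max / s)
  off <- seq(-half, half, by = s)
  g <- expand.grid(x = off, y = off)
  d2 <- g$x^2 + g$y^2
  keep <- d2 <= (3 * sig_max)^2
  g <- g[keep, , drop = FALSE]; d2 <- d2[keep]
  wc <- exp(-d2 / (2 * p$sigma_center_um^2)); wc <- wc / sum(wc)
  ws <- if (p$k_surr > 0) {
    w <- exp(-d2 / (2 * p$sigma_surround_um^2)); w / sum(w)
  } else rep(0, length(d2))
  list(x = g$x + cell$center_um[1], y = g$y + cell$center_um[2],
       w_center = wc, w_surround = ws, extent_um = 3 * sig_max)
}

# Map subunits onto stimulus pixels: average of pixel centers inside the
# subunit's square catchment (side = spacing), or the nearest pixel if none.
# Returns per-subunit-group pixel index sets with pooled weights (subunits
# with identical catchments are merged; the local signal, and hence the
# nonlinearity output, is identical within a group).
subunit_pixel_groups <- function(cell, stim) {
  lay <- subunit_layout(cell)
  pc <- pixel_centers(stim)
  H <- dim(stim$frames)[2]
  s2 <- cell$subunit_spacing_um / 2
  n_sub <- length(lay$x)
  keys <- character(n_sub)
  idx_list <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    cols <- which(pc$x >= lay$x[i] - s2 & pc$x < lay$x[i] + s2)
    rows <- which(pc$y >= lay$y[i] - s2 & pc$y < lay$y[i] + s2)
    if (length(cols) == 0) cols <- which.min(abs(pc$x - lay$x[i]))
    if (length(rows) == 0) rows <- which.min(abs(pc$y - lay$y[i]))
    idx <- as.vector(outer(rows, (cols - 1) * H, "+"))
    idx_list[[i]] <- idx
    keys[i] <- paste(idx, collapse = ",")
  }
  grp <- match(keys, unique(keys))
  n_grp <- max(grp)
  list(idx = idx_list[!duplicated(grp)],
       w_center = as.vector(tapply(lay$w_center, grp, sum)[as.character(seq_len(n_grp))]),
       w_surround = as.vector(tapply(lay$w_surround, grp, sum)[as.character(seq_len(n_grp))]),
       extent_um = lay$extent_um)
}

# Causal FFT convolution of all columns of `x` with kernel `k`, chunked
# (overlap-save) to bound memory.  Output has the same number of rows as x.
conv_causal_cols <- function(x, k, block = 65536L) {
  n <- nrow(x); m <- ncol(x); L <- length(k)
  out <- matrix(0, n, m)
  nfft <- stats::nextn(min(block, n) + L - 1, 2)
  step <- nfft - L + 1
  kf <- stats::fft(c(k, rep(0, nfft - L)))
  t0 <- 1
  while (t0 <= n) {
    t1 <- min(t0 + step - 1, n)
    lo <- max(1, t0 - L + 1)
    seg <- x[lo:t1, , drop = FALSE]
    pad_pre <- (L - 1) - (t0 - lo)
    nseg <- pad_pre + nrow(seg)
    buf <- matrix(0, nfft, m)
    buf[pad_pre + seq_len(nrow(seg)), ] <- seg
    cf <- stats::mvfft(stats::mvfft(buf) * kf, inverse = TRUE) / nfft
    out[t0:t1, ] <- Re(cf[(L - 1) + seq_len(t1 - t0 + 1), , drop = FALSE])
    t0 <- t1 + 1
  }
  out
}

# Slow baseline drift: Gaussian process low-pass filtered at ~1/timescale,
# generated at 10 Hz and interpolated to the simulation rate.
make_drift <- function(n_ms, amplitude_mv, timescale_s) {
  if (amplitude_mv <= 0) return(rep(0, n_ms))
  gen_rate <- 10
  n_g <- max(ceiling(n_ms / SIM_RATE_HZ * gen_rate) + 8 * gen_rate, 64)
  w <- stats::rnorm(n_g)
  bf <- signal::butter(2, min(1 / timescale_s, gen_rate / 2 * 0.9) /
                         (gen_rate / 2), type = "low")
  d <- signal::filtfilt(bf, w)
  d <- d[-(seq_len(4 * gen_rate))]          # discard filter warm-up
  sdd <- stats::sd(d)
  if (sdd > 0) d <- d * (amplitude_mv / sdd)
  stats::approx(seq_along(d) / gen_rate, d,
                xout = seq_len(n_ms) / SIM_RATE_HZ, rule = 2)$y
}

#' Simulate the membrane-potential response of a subunit-model cell
#'
#' Runs the full generative pipeline at 1 kHz: frame-hold upsampling of the
#' stimulus, per-subunit spatial averaging, temporal filtering with the
#' biphasic kernel (sign-flipped for OFF cells), the static subunit
#' nonlinearity, Gaussian-weighted pooling (minus the suppressive surround),
#' driving-force scaling of the light input, the soma output function, and
#' additive noise plus slow drift.
#'
#' @param cell a [subunit_cell()].
#' @param stim a [frame_sequence()]; must cover the cell's 3-sigma pooling
#'   extent.
#' @param seed integer seed for noise and drift.
#' @param injected_current_pa somatic current injection; shifts the baseline
#'   by `I * R_in` and rescales the light drive by the driving-force ratio
#'   `(E_rev - V_base) / (E_rev - V_rest)`.
#' @param n_trials number of trials (same drive, fresh noise/drift).
#' @return a [voltage_trace()] (or a list of them when `n_trials > 1`).
#' @export
simulate_voltage <- function(cell, stim, seed = 1, injected_current_pa = 0,
                             n_trials = 1) {
  stopifnot(inherits(cell, "subunit_cell"), inherits(stim, "frame_sequence"))
  d <- dim(stim$frames)
  ext_x <- c(stim$origin_um[1], stim$origin_um[1] + d[3] * stim$pixel_size_um)
  ext_y <- c(stim$origin_um[2], stim$origin_um[2] + d[2] * stim$pixel_size_um)
  grp <- subunit_pixel_groups(cell, stim)
  need <- grp$extent_um
  if (cell$center_um[1] - need < ext_x[1] - stim$pixel_size_um / 2 ||
      cell$center_um[1] + need > ext_x[2] + stim$pixel_size_um / 2 ||
      cell$center_um[2] - need < ext_y[1] - stim$pixel_size_um / 2 ||
      cell$center_um[2] + need > ext_y[2] + stim$pixel_size_um / 2)
    stop(sprintf(
      "stimulus too small for the cell's pooling extent: needs +-%.0f um around (%.0f, %.0f)",
      need, cell$center_um[1], cell$center_um[2]))
  drive <- compute_drive(cell, stim, grp)
  v_base <- cell$v_rest_mv + injected_current_pa * cell$r_in_mohm / 1000
  dfr <- if (cell$e_rev_mv == cell$v_rest_mv) 1 else
    (cell$e_rev_mv - v_base) / (cell$e_rev_mv - cell$v_rest_mv)
  light <- soma_fun(cell$soma)(cell$g_gain_mv * drive * dfr)
  n_ms <- length(light)
  traces <- lapply(seq_len(n_trials), function(tr) {
    with_seed(child_seed(seed, paste0("trial", tr)), {
      noise <- if (cell$noise_sd_mv > 0)
        stats::rnorm(n_ms, 0, cell$noise_sd_mv) else 0
      dr <- make_drift(n_ms, cell$drift$amplitude_mv, cell$drift$timescale_s)
      voltage_trace(v_base + light + noise + dr, SIM_RATE_HZ, t0_s = 0,
                    trial_id = tr)
    })
  })
  if (n_trials == 1) traces[[1]] else traces
}

# Pooled subunit drive D(t) at 1 kHz (before gain/driving force/soma).
compute_drive <- function(cell, stim, grp = subunit_pixel_groups(cell, stim)) {
  d <- dim(stim$frames)
  X <- matrix(stim$frames, nrow = d[1])
  u <- vapply(grp$idx, function(idx) {
    if (length(idx) == 1) X[, idx] else rowMeans(X[, idx, drop = FALSE])
  }, numeric(d[1]))
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  n_ms <- round(d[1] / stim$frame_rate_hz * SIM_RATE_HZ)
  f_ms <- pmin(floor((seq_len(n_ms) - 1) / SIM_RATE_HZ *
                       stim$frame_rate_hz) + 1, d[1])
  k <- biphasic_kernel(cell$kernel$peak_latency_ms, cell$kernel$biphasic_ratio,
                       cell$kernel$duration_ms, SIM_RATE_HZ)
  if (cell$polarity == "OFF") k <- -k
  phi <- subunit_nl_fun(cell$nonlinearity)
  x <- conv_causal_cols(u[f_ms, , drop = FALSE], k)
  y <- phi(x)
  as.vector(y %*% grp$w_center) -
    cell$pooling$k_surr * as.vector(y %*% grp$w_surround)
}

#' Draw a reproducible population of subunit-model cells
#'
#' Each entry of `pop_cfg` is either a single value (fixed) or a length-2
#' numeric range sampled uniformly.  Recognized entries: `threshold`,
#' `sigma_center_um`, `peak_latency_ms`, `biphasic_ratio`, plus
#' `nonlinearity_type` (`"threshold_linear"` or `"linear"`) and any fixed
#' [subunit_cell()] arguments in `...`.
#'
#' @param pop_cfg list of parameter distributions (see
#'   [default_population_cfg()]).
#' @param n number of cells.
#' @param seed integer seed.
#' @param ... fixed arguments forwarded to [subunit_cell()].
#' @return list of `n` [subunit_cell()] objects; ground-truth draws are
#'   attached as the `"params"` attribute (a data frame).
#' @export
sample_cell_population <- function(pop_cfg = default_population_cfg(), n,
                                   seed = 1, ...) {
  if (n < 1) stop("`n` must be >= 1")
  draw <- function(spec, m) {
    if (length(spec) == 1) rep(spec, m)
    else if (length(spec) == 2) {
      if (spec[2] < spec[1]) stop("degenerate distribution: upper < lower")
      stats::runif(m, spec[1], spec[2])
    } else stop("distribution must be a value or a range")
  }
  with_seed(child_seed(seed, "population"), {
    params <- data.frame(
      threshold = draw(pop_cfg$threshold %||% 0, n),
      sigma_center_um = draw(pop_cfg$sigma_center_um %||% 35, n),
      peak_latency_ms = draw(pop_cfg$peak_latency_ms %||% 50, n),
      biphasic_ratio = draw(pop_cfg$biphasic_ratio %||% 0.3, n))
  })
  nl_type <- pop_cfg$nonlinearity_type %||% "threshold_linear"
  cells <- lapply(seq_len(n), function(i) {
    subunit_cell(
      nonlinearity = if (nl_type == "linear") list(type = "linear")
        else list(type = "threshold_linear",
                  threshold = params$threshold[i]),
      pooling = list(sigma_center_um = params$sigma_center_um[i]),
      kernel = list(peak_latency_ms = params$peak_latency_ms[i],
                    biphasic_ratio = params$biphasic_ratio[i]),
      ...)
  })
  attr(cells, "params") <- params
  cells
}

#' Default population configuration spanning linear to rectifying subunits
#'
#' Thresholds are uniform on `[-2, 0]` generator units: at -2 the
#' threshold-linear transfer is effectively affine over the stimulus-driven
#' signal range (linear spatial integration), at 0 it is half-wave
#' rectifying.
#'
#' @return list of parameter ranges for [sample_cell_population()].
#' @export
default_population_cfg <- function() {
  list(threshold = c(-2, 0), sigma_center_um = c(25, 45),
       peak_latency_ms = c(40, 80), biphasic_ratio = c(0.4, 0.6),
       nonlinearity_type = "threshold_linear")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
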