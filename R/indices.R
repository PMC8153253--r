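# Scalar response indices: hyperpolarization, output-nonlinearity, spatial
# nonlinearity (spots and gratings), sustained-transient, latency,
# center-surround / difference-of-Gaussians spot profile, temporal-frequency
# sweep amplitude, oscillation frequency, and the ganglion-cell spatial
# scale from reversing gratings.

#' Hyperpolarization index
#'
#' `HPi = (V_dep + V_hyp) / (|V_dep| + |V_hyp|)` where `V_dep` is the peak
#' (depolarizing) voltage during preferred contrast and `V_hyp` the minimum
#' during non-preferred contrast, both baseline-subtracted.  Near 0 for
#' linear cells, near 1 for fully rectifying cells (no hyperpolarization),
#' negative when hyperpolarization dominates.
#'
#' @param preferred baselined averaged response to preferred contrast (its
#'   maximum is taken as `V_dep`), or the scalar `V_dep` itself.
#' @param nonpreferred baselined averaged response to non-preferred contrast
#'   (its minimum is `V_hyp`), or the scalar `V_hyp`.
#' @return HPi in `[-1, 1]`, or `NA` when both extrema are zero.
#' @export
hyperpolarization_index <- function(preferred, nonpreferred) {
  v_dep <- max(preferred)
  v_hyp <- min(nonpreferred)
  den <- abs(v_dep) + abs(v_hyp)
  if (den == 0) return(NA_real_)
  (v_dep + v_hyp) / den
}

#' Output nonlinearity index
#'
#' Straight lines are fitted separately to the output-function bins with
#' positive and with negative generator signal; with slopes `S_pos` and
#' `S_neg`, `ONi = (S_pos - S_neg) / (|S_pos| + |S_neg|)`.  Near 0 for
#' linear output functions, near 1 for rectification, negative for
#' saturating responses (weaker gain at preferred contrast).
#'
#' @param outfn an `"output_function"` (or data frame with `generator`,
#'   `voltage`).
#' @return ONi in `[-1, 1]`, or `NA` with fewer than 3 bins on a side.
#' @export
output_nonlinearity_index <- function(outfn) {
  pos <- outfn$generator > 0
  if (sum(pos) < 3 || sum(!pos) < 3) return(NA_real_)
  s_pos <- stats::coef(stats::lm(voltage ~ generator, outfn[pos, ]))[2]
  s_neg <- stats::coef(stats::lm(voltage ~ generator, outfn[!pos, ]))[2]
  den <- abs(s_pos) + abs(s_neg)
  if (den == 0) return(NA_real_)
  unname((s_pos - s_neg) / den)
}

# Fourier power of a cycle average at an integer frequency (Hz); the cycle
# length defines the frequency resolution.
cycle_power <- function(x, rate_hz, freq_hz) {
  n <- length(x)
  dur_s <- n / rate_hz
  bin <- freq_hz * dur_s
  if (abs(bin - round(bin)) > 1e-9)
    stop("frequency is not a harmonic of the cycle")
  Mod(stats::fft(x)[round(bin) + 1])^2
}

#' Spatial nonlinearity index from patterned-spot responses
#'
#' Combined Fourier power at the relevant higher harmonics (2 Hz and 4 Hz)
#' of the cycle-averaged response to a spatially structured spot, normalized
#' by the 1 Hz power of the uniform contrast-reversing spot:
#' `SNi = (P_pat(2) + P_pat(4)) / P_unif(1)`.  Values near zero indicate no
#' frequency doubling (linear spatial integration).
#'
#' @param pattern_responses named list of mean-subtracted 1-s cycle averages
#'   (see [cycle_average()]), one per spatial pattern.
#' @param uniform_response mean-subtracted 1-s cycle average of the uniform
#'   reversing spot (interpolate between the two nearest diameters first if
#'   the tested uniform diameters do not include the pattern diameter).
#' @param rate_hz sampling rate of the cycle averages.
#' @param max_patterns patterns entering `sni_max` (the fine 10 um
#'   checkerboard is excluded, as it was not recorded for all cells).
#' @param noise_floor minimum admissible 1 Hz uniform power; below it the
#'   index is returned as `NA`.
#' @return list with `sni` (per pattern) and `sni_max`.
#' @export
spatial_nonlinearity_index <- function(pattern_responses, uniform_response,
                                       rate_hz,
                                       max_patterns = c("halves", "quarters",
                                                        "check25"),
                                       noise_floor = 0) {
  p1 <- cycle_power(uniform_response, rate_hz, 1)
  if (p1 <= noise_floor || p1 == 0)
    return(list(sni = rep(NA_real_, length(pattern_responses)),
                sni_max = NA_real_, flagged = TRUE))
  sni <- vapply(pattern_responses, function(x) {
    (cycle_power(x, rate_hz, 2) + cycle_power(x, rate_hz, 4)) / p1
  }, numeric(1))
  sel <- intersect(names(sni), max_patterns)
  if (length(sel) == 0) sel <- names(sni)
  list(sni = sni, sni_max = max(sni[sel]), flagged = FALSE)
}

#' Linear interpolation between uniform-spot traces of two diameters
#'
#' @param trace_lo,trace_hi cycle averages for the nearest smaller/larger
#'   tested uniform-spot diameters.
#' @param d_lo,d_hi,d_target the respective diameters (um).
#' @return interpolated trace at `d_target`.
#' @export
interpolate_uniform_traces <- function(trace_lo, trace_hi, d_lo, d_hi,
                                       d_target) {
  if (d_hi == d_lo) return(trace_lo)
  w <- (d_target - d_lo) / (d_hi - d_lo)
  (1 - w) * trace_lo + w * trace_hi
}

#' Spatial nonlinearity index for contrast-reversing gratings
#'
#' For each spatial period: the mean power at 2 Hz plus 4 Hz, averaged over
#' all spatial phases, divided by the maximum 1 Hz power over all phases.
#' The maximum over periods summarizes the cell.
#'
#' @param phase_responses list (one entry per spatial period) of lists of
#'   mean-subtracted 1-s cycle averages, one per spatial phase.
#' @param rate_hz sampling rate of the cycle averages.
#' @return list with `per_period` and `sni_grating` (max over periods).
#' @export
grating_nonlinearity_index <- function(phase_responses, rate_hz) {
  per <- vapply(phase_responses, function(phases) {
    if (length(phases) == 0) return(NA_real_)
    p24 <- vapply(phases, function(x)
      cycle_power(x, rate_hz, 2) + cycle_power(x, rate_hz, 4), numeric(1))
    p1 <- vapply(phases, function(x) cycle_power(x, rate_hz, 1), numeric(1))
    mean(p24) / max(p1)
  }, numeric(1))
  list(per_period = per, sni_grating = max(per, na.rm = TRUE))
}

#' Sustained-transient index
#'
#' Ratio of the steady-state response (mean voltage over the last 50 ms of
#' the spot presentation) to the peak response, for a flashed spot of
#' preferred contrast.  Near 1 for sustained, near 0 for transient cells.
#'
#' @param response baselined averaged response, starting at spot onset.
#' @param rate_hz sampling rate.
#' @param spot_duration_s spot presentation time (0.5 s).
#' @param steady_window_s averaging window at the end of the presentation.
#' @param noise_floor peak responses at or below this level give `NA`.
#' @return STi (may exceed `[0, 1]` for noisy traces).
#' @export
sustained_transient_index <- function(response, rate_hz,
                                      spot_duration_s = 0.5,
                                      steady_window_s = 0.05,
                                      noise_floor = 0) {
  n_on <- round(spot_duration_s * rate_hz)
  stopifnot(length(response) >= n_on)
  v_peak <- max(response[seq_len(n_on)])
  if (v_peak <= noise_floor) return(NA_real_)
  i0 <- round((spot_duration_s - steady_window_s) * rate_hz) + 1
  v_ss <- mean(response[i0:n_on])
  v_ss / v_peak
}

#' Response onset and time-to-peak latency
#'
#' Onset: time of the first sample after spot onset exceeding 3 standard
#' deviations of the baseline in the preferred direction.  Time-to-peak:
#' time from stimulus onset to the maximum response.
#'
#' @param response baselined averaged response starting at spot onset.
#' @param baseline_sd standard deviation of the pre-stimulus baseline.
#' @param rate_hz sampling rate.
#' @param spot_duration_s search window for the crossing.
#' @return list with `onset_ms` (`NA` when no crossing occurs) and
#'   `time_to_peak_ms`.
#' @export
response_latency <- function(response, baseline_sd, rate_hz,
                             spot_duration_s = 0.5) {
  n_on <- min(round(spot_duration_s * rate_hz), length(response))
  seg <- response[seq_len(n_on)]
  cross <- which(seg > 3 * baseline_sd)
  list(onset_ms = if (length(cross)) (cross[1] - 1) * 1000 / rate_hz
         else NA_real_,
       time_to_peak_ms = (which.max(seg) - 1) * 1000 / rate_hz)
}

#' Difference-of-Gaussians fit of peak response versus spot size
#'
#' Fits `V(r) = k_c (1 - exp(-r^2 / (2 s_c^2))) - k_s (1 - exp(-r^2 /
#' (2 s_s^2)))` (r = spot radius) to the peak preferred-contrast responses
#' across spot diameters; constraints `k_c, k_s >= 0`, `s_s >= s_c`.  Also
#' reports the center-surround index `1 - V_largespot / V_allspots`
#' (computed from the measured peaks over spots up to 500 um) and the local
#' spot: the tested diameter closest to the estimated receptive-field width
#' of `3 s_c` (falling back to the white-noise RF diameter when the fitted
#' width exceeds 250 um).
#'
#' @param diameters_um tested spot diameters.
#' @param peaks_mv peak baselined response per diameter.
#' @param rf_diameter_um optional white-noise receptive-field diameter used
#'   as fallback.
#' @param large_spot_um diameter defining the "large spot" (500).
#' @return list with the fitted parameters, `center_surround_index`,
#'   `local_spot_diameter_um`, `rf_width_um` (= 3 s_c), `converged` and
#'   `used_fallback`.
#' @export
fit_dog_profile <- function(diameters_um, peaks_mv, rf_diameter_um = NULL,
                            large_spot_um = 500) {
  stopifnot(length(diameters_um) == length(peaks_mv),
            length(diameters_um) >= 4)
  r <- diameters_um / 2
  df <- data.frame(r = r, v = peaks_mv)
  i_pk <- which.max(peaks_mv)
  start <- list(kc = max(peaks_mv), sc = max(r[i_pk] / 2, 5),
                ks = max(max(peaks_mv) - peaks_mv[length(peaks_mv)], 0.01),
                ds = max(r) / 2)
  fit <- try(minpack.lm::nlsLM(
    v ~ kc * (1 - exp(-r^2 / (2 * sc^2))) -
      ks * (1 - exp(-r^2 / (2 * (sc + ds)^2))),
    data = df, start = start,
    lower = c(kc = 0, sc = 1, ks = 0, ds = 0),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  converged <- !inherits(fit, "try-error")
  small <- diameters_um <= large_spot_um
  v_all <- max(peaks_mv[small])
  i_large <- which.min(abs(diameters_um - large_spot_um))
  v_large <- peaks_mv[i_large]
  csi <- 1 - v_large / v_all
  if (converged) {
    cf <- stats::coef(fit)
    rf_width <- 3 * cf[["sc"]]
    used_fallback <- rf_width > 250 && !is.null(rf_diameter_um)
    target <- if (used_fallback) rf_diameter_um else rf_width
    list(k_center = cf[["kc"]], sigma_center_um = cf[["sc"]],
         k_surr = cf[["ks"]], sigma_surround_um = cf[["sc"]] + cf[["ds"]],
         rf_width_um = rf_width,
         center_surround_index = csi,
         local_spot_diameter_um = diameters_um[which.min(abs(diameters_um -
                                                               target))],
         converged = TRUE, used_fallback = used_fallback)
  } else {
    target <- if (!is.null(rf_diameter_um)) rf_diameter_um else
      diameters_um[i_pk]
    list(k_center = NA_real_, sigma_center_um = NA_real_, k_surr = NA_real_,
         sigma_surround_um = NA_real_, rf_width_um = NA_real_,
         center_surround_index = csi,
         local_spot_diameter_um = diameters_um[which.min(abs(diameters_um -
                                                               target))],
         converged = FALSE, used_fallback = TRUE)
  }
}

#' Response amplitude modulation across temporal frequencies
#'
#' The amplitude modulation of a trial-averaged response is the difference
#' between its maximum and minimum — a measure that remains stable at low
#' reversal frequencies where responses are not sinusoid-like.
#'
#' @param responses named list of trial-averaged response vectors, one per
#'   condition/frequency.
#' @return named numeric vector of max - min per condition.
#' @export
frequency_sweep_amplitude <- function(responses) {
  vapply(responses, function(x) max(x) - min(x), numeric(1))
}

#' Oscillation frequency of a full-field step response
#'
#' Fourier peak frequency of the mean-subtracted response in a window from
#' 250 ms after stimulus onset to 50 ms after the end of a 1 s contrast
#' step (800 ms analysis window).
#'
#' @param response baselined averaged step response starting at onset.
#' @param rate_hz sampling rate.
#' @param step_duration_s contrast-step duration.
#' @param window_start_s analysis-window start after onset.
#' @param window_end_after_s analysis-window end after step offset.
#' @param min_peak_ratio peak power must exceed this multiple of the median
#'   spectral power to count as confident; for a flat (white-noise)
#'   spectrum of a few hundred bins the expected maximum-to-median ratio
#'   stays near `log(n)/log(2)`, well below the default.
#' @return list with `frequency_hz`, `power` and `confident`.
#' @export
oscillation_frequency <- function(response, rate_hz, step_duration_s = 1,
                                  window_start_s = 0.25,
                                  window_end_after_s = 0.05,
                                  min_peak_ratio = 20) {
  i0 <- round(window_start_s * rate_hz) + 1
  i1 <- round((step_duration_s + window_end_after_s) * rate_hz)
  stopifnot(i1 <= length(response), i1 > i0)
  x <- response[i0:i1]
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- 2:floor(n / 2)
  freqs <- (half - 1) * rate_hz / n
  pk <- which.max(p[half])
  med <- stats::median(p[half])
  list(frequency_hz = freqs[pk], power = p[half][pk],
       confident = med > 0 && p[half][pk] / med >= min_peak_ratio)
}

#' Spatial scale of grating sensitivity from a logistic fit
#'
#' Fits a 4-parameter logistic function to peak response (e.g. ganglion-cell
#' peak firing rate) versus grating bar width; the midpoint parameter is the
#' scale of spatial sensitivity.
#'
#' @param bar_widths_um grating bar widths.
#' @param peak_responses peak response per bar width.
#' @return list with `scale_um` (logistic midpoint), the full coefficient
#'   set, and `flagged` (fit failure, flat or non-monotone data).
#' @export
grating_spatial_scale <- function(bar_widths_um, peak_responses) {
  stopifnot(length(bar_widths_um) == length(peak_responses))
  if (stats::sd(peak_responses) == 0)
    return(list(scale_um = NA_real_, coef = NULL, flagged = TRUE))
  rho <- suppressWarnings(
    stats::cor(bar_widths_um, peak_responses, method = "spearman"))
  o <- order(bar_widths_um)
  df <- data.frame(x = bar_widths_um[o], y = peak_responses[o])
  # initialize the midpoint at the steepest rise
  i_jump <- which.max(diff(df$y) / diff(df$x))
  fit <- try(minpack.lm::nlsLM(
    y ~ a + (b - a) / (1 + exp(-(x - m) / s)), data = df,
    start = list(a = min(df$y), b = max(df$y),
                 m = (df$x[i_jump] + df$x[i_jump + 1]) / 2,
                 s = max((df$x[i_jump + 1] - df$x[i_jump]) / 4, 0.5)),
    lower = c(a = -Inf, b = -Inf, m = min(bar_widths_um) / 4, s = 0.1),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (!inherits(fit, "try-error")) {
    cf <- stats::coef(fit)
    return(list(scale_um = unname(cf["m"]), coef = cf,
                flagged = is.na(rho) || rho <= 0))
  }
  # degenerate (step-like) data: half-maximum crossing as the midpoint
  half <- (min(df$y) + max(df$y)) / 2
  m <- stats::approx(df$y, df$x, xout = half, ties = mean)$y
  list(scale_um = m, coef = NULL, flagged = is.na(rho) || rho <= 0)
}
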