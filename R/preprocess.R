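# Trace conditioning: running-median filtering + decimation of raw 20 kHz
# recordings, high-pass detrending, baseline-subtracted epoch averaging,
# cycle averaging of periodic responses, and binning to stimulus frames.

#' Condition a raw 20 kHz trace to 1 ms resolution
#'
#' A centered running median (window of 80 samples; edge windows shrink)
#' followed by stride-20 decimation, reproducing the standard conditioning
#' of sharp-electrode recordings.  Only the medians at the retained samples
#' are computed.
#'
#' @param raw a [voltage_trace()] at 20 kHz.
#' @param median_window running-median window in samples.
#' @param decimate decimation stride.
#' @return a [voltage_trace()] at 1 kHz.
#' @export
condition_raw_trace <- function(raw, median_window = 80, decimate = 20) {
  stopifnot(inherits(raw, "voltage_trace"))
  x <- raw$samples_mv
  n <- length(x)
  if (n < median_window)
    stop(sprintf("trace (%d samples) shorter than the median window (%d)",
                 n, median_window))
  half_lo <- floor((median_window - 1) / 2)
  half_hi <- median_window - 1 - half_lo
  keep <- seq.int(decimate, n, by = decimate)
  med <- vapply(keep, function(i) {
    stats::median(x[max(1, i - half_lo):min(n, i + half_hi)])
  }, numeric(1))
  voltage_trace(med, raw$rate_hz / decimate,
                t0_s = raw$t0_s + (decimate - 1) / raw$rate_hz,
                trial_id = raw$trial_id)
}

#' High-pass detrend a conditioned trace
#'
#' Zero-phase (forward-backward) Butterworth high-pass at 0.1 Hz; removes DC
#' and slow baseline drift without distorting response latencies.
#'
#' @param trace a [voltage_trace()].
#' @param cutoff_hz high-pass cutoff frequency.
#' @param order Butterworth order (applied twice by filtfilt).
#' @return the detrended [voltage_trace()].
#' @export
detrend_highpass <- function(trace, cutoff_hz = 0.1, order = 2) {
  stopifnot(inherits(trace, "voltage_trace"))
  bf <- signal::butter(order, cutoff_hz / (trace$rate_hz / 2), type = "high")
  # remove the mean first: shrinks the filter's edge transients, and the
  # high-pass removes any remaining DC anyway
  y <- signal::filtfilt(bf, trace$samples_mv - mean(trace$samples_mv))
  voltage_trace(y, trace$rate_hz, trace$t0_s, trace$trial_id)
}

#' Baseline-subtracted averaging over trials and conditions
#'
#' For each epoch the mean over the `baseline_window_ms` preceding the onset
#' is subtracted; baselined responses are then averaged across trials of the
#' same condition.
#'
#' @param traces a [voltage_trace()] or list of them (one per trial).
#' @param epochs data frame with columns `trial` (index into `traces`),
#'   `onset_s`, `offset_s` and `condition`.
#' @param baseline_window_ms length of the pre-onset baseline window.
#' @return named list (one entry per condition) with `time_s` (relative to
#'   onset, including the baseline window), `mean_mv`, `sd_mv`, `n_trials`,
#'   and `baseline_sd_mv` (per-trial SD within the baseline window, averaged).
#' @export
epoch_average <- function(traces, epochs, baseline_window_ms = 200) {
  if (inherits(traces, "voltage_trace")) traces <- list(traces)
  stopifnot(is.data.frame(epochs),
            all(c("trial", "onset_s", "offset_s", "condition") %in%
                  names(epochs)))
  out <- list()
  for (cond in unique(epochs$condition)) {
    ep <- epochs[epochs$condition == cond, , drop = FALSE]
    segs <- NULL
    bl_sd <- numeric(0)
    for (j in seq_len(nrow(ep))) {
      tr <- traces[[ep$trial[j]]]
      i_on <- round((ep$onset_s[j] - tr$t0_s) * tr$rate_hz) + 1
      i_off <- round((ep$offset_s[j] - tr$t0_s) * tr$rate_hz)
      n_bl <- round(baseline_window_ms / 1000 * tr$rate_hz)
      if (i_on - n_bl < 1)
        stop("baseline window precedes the start of the trace")
      if (i_off > length(tr$samples_mv))
        stop("epoch extends past the end of the trace")
      seg <- tr$samples_mv[(i_on - n_bl):i_off]
      bl <- tr$samples_mv[(i_on - n_bl):(i_on - 1)]
      seg <- seg - mean(bl)
      bl_sd <- c(bl_sd, stats::sd(bl))
      segs <- if (is.null(segs)) matrix(seg, nrow = 1) else
        rbind(segs, seg[seq_len(ncol(segs))])
      rate <- tr$rate_hz; n_bl_keep <- n_bl
    }
    out[[as.character(cond)]] <- list(
      time_s = (seq_len(ncol(segs)) - n_bl_keep - 1) / rate,
      mean_mv = colMeans(segs),
      sd_mv = if (nrow(segs) > 1) apply(segs, 2, stats::sd) else
        rep(NA_real_, ncol(segs)),
      n_trials = nrow(segs),
      baseline_sd_mv = mean(bl_sd),
      rate_hz = rate)
  }
  out
}

#' Average voltage per stimulus frame interval
#'
#' One mean membrane potential per interval `[t_i, t_{i+1})`; the final
#' interval ends one median frame step after the last onset (clipped to the
#' trace).
#'
#' @param trace a [voltage_trace()].
#' @param frame_times_s monotone increasing vector of frame onset times.
#' @return numeric vector with one mean voltage per frame.
#' @export
bin_voltage_to_frames <- function(trace, frame_times_s) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (is.unsorted(frame_times_s, strictly = TRUE))
    stop("`frame_times_s` must be strictly increasing")
  tt <- trace_times(trace)
  if (frame_times_s[1] < tt[1] - 1e-9 ||
      frame_times_s[length(frame_times_s)] > tt[length(tt)] + 1e-9)
    stop("frame times outside the trace")
  dt <- stats::median(diff(frame_times_s))
  edges <- c(frame_times_s, frame_times_s[length(frame_times_s)] + dt)
  bin <- findInterval(tt, edges, left.open = FALSE)
  ok <- bin >= 1 & bin <= length(frame_times_s)
  means <- rep(NA_real_, length(frame_times_s))
  agg <- tapply(trace$samples_mv[ok], bin[ok], mean)
  means[as.integer(names(agg))] <- agg
  means
}

#' Average response over stimulus cycles
#'
#' Folds a periodic response into cycles of `period_s`, optionally dropping
#' the first cycle (stimulus-onset artifact) and subtracting the mean of the
#' resulting cycle average.
#'
#' @param x a [voltage_trace()] or numeric vector.
#' @param period_s cycle duration in seconds.
#' @param rate_hz sampling rate (taken from the trace when omitted).
#' @param start_s time of the first cycle start within the input.
#' @param drop_first drop the first cycle before averaging.
#' @param demean subtract the mean of the cycle average.
#' @return numeric vector of length `period_s * rate_hz`.
#' @export
cycle_average <- function(x, period_s, rate_hz = NULL, start_s = 0,
                          drop_first = TRUE, demean = TRUE) {
  if (inherits(x, "voltage_trace")) {
    rate_hz <- x$rate_hz
    x <- x$samples_mv[trace_times(x) >= x$t0_s + start_s - 1e-12]
  } else if (start_s > 0) {
    x <- x[-seq_len(round(start_s * rate_hz))]
  }
  if (is.null(rate_hz)) stop("`rate_hz` required for plain vectors")
  np <- round(period_s * rate_hz)
  n_cyc <- length(x) %/% np
  if (n_cyc < 1 + drop_first) stop("fewer than the required number of cycles")
  m <- matrix(x[seq_len(n_cyc * np)], nrow = np)
  if (drop_first) m <- m[, -1, drop = FALSE]
  avg <- rowMeans(m)
  if (demean) avg <- avg - mean(avg)
  avg
}

#' Gaussian-weighted moving average
#'
#' Smoothing used for current-injection response traces (SD 10 ms within a
#' 50 ms window at 1 kHz).
#'
#' @param x numeric vector or [voltage_trace()].
#' @param sd_samples Gaussian SD in samples.
#' @param window_samples total window length in samples.
#' @return smoothed object of the same type.
#' @export
gaussian_smooth <- function(x, sd_samples = 10, window_samples = 50) {
  if (inherits(x, "voltage_trace")) {
    x$samples_mv <- gaussian_smooth(x$samples_mv, sd_samples, window_samples)
    return(x)
  }
  half <- floor(window_samples / 2)
  w <- stats::dnorm(-half:half, sd = sd_samples)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  stats::filter(xp, w / sum(w), sides = 2)[(half + 1):(half + n)]
}
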