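# Current-injection analyses: input resistance from the I-V slope and the
# reversal potential of the light-driven input, extrapolated from how the
# split-spot response amplitude varies with the baseline membrane potential.

#' Input resistance from current-voltage pairs
#'
#' Straight-line fit of baseline membrane potential versus injected
#' current; the slope is the input resistance.  An electrode I-V curve (or
#' a scalar electrode resistance) measured in the bath corrects for the
#' voltage drop across the electrode.
#'
#' @param currents_pa injected currents (pA), at least two distinct values.
#' @param baselines_mv baseline membrane potential per current (mV).
#' @param electrode_iv optional correction: a data frame with columns
#'   `current_pa`, `voltage_mv` (interpolated per current) or a single
#'   electrode resistance in megaohms.
#' @return list with `r_in_mohm`, its standard error and the fit.
#' @export
input_resistance <- function(currents_pa, baselines_mv, electrode_iv = NULL) {
  stopifnot(length(currents_pa) == length(baselines_mv))
  if (length(unique(currents_pa)) < 2)
    stop("need at least two distinct current levels")
  v <- baselines_mv
  if (!is.null(electrode_iv)) {
    drop_mv <- if (is.data.frame(electrode_iv)) {
      stats::approx(electrode_iv$current_pa, electrode_iv$voltage_mv,
                    xout = currents_pa, rule = 2)$y
    } else currents_pa * electrode_iv / 1000
    v <- v - drop_mv
  }
  fit <- stats::lm(v ~ currents_pa)
  sl <- suppressWarnings(summary(fit))$coefficients
  list(r_in_mohm = unname(sl["currents_pa", "Estimate"] * 1000),
       se_mohm = unname(sl["currents_pa", "Std. Error"] * 1000),
       fit = fit)
}

#' Reversal potential from response amplitude versus baseline potential
#'
#' Least-squares line of maximum light-evoked response amplitude against
#' the (electrode-corrected) baseline membrane potential under current
#' injection; the x-axis intercept estimates the reversal potential of the
#' input driving the response.  A non-negative slope (response not
#' decreasing with depolarization) flags the intercept as unreliable.
#'
#' @param peak_responses_mv maximum baseline-subtracted response per
#'   current level (trial-averaged, Gaussian-smoothed traces).
#' @param baselines_mv corrected baseline membrane potential per level.
#' @return list with `e_rev_mv` (x intercept), `se_mv` (delta-method
#'   standard error), `slope`, and `flagged`.
#' @export
reversal_potential <- function(peak_responses_mv, baselines_mv) {
  stopifnot(length(peak_responses_mv) == length(baselines_mv),
            length(baselines_mv) >= 3)
  fit <- stats::lm(peak_responses_mv ~ baselines_mv)
  cf <- stats::coef(fit)
  a <- cf[[1]]; b <- cf[[2]]
  e_rev <- -a / b
  V <- suppressWarnings(stats::vcov(fit))
  grad <- c(-1 / b, a / b^2)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  s <- suppressWarnings(summary(fit))$coefficients
  p_slope <- s["baselines_mv", "Pr(>|t|)"]
  list(e_rev_mv = unname(e_rev), se_mv = se, slope = unname(b),
       flagged = b >= 0 || (is.finite(p_slope) && p_slope > 0.05 && b > -1e-12),
       fit = fit)
}

#' Simulate the current-injection split-spot protocol and extrapolate E_rev
#'
#' For each current level, the cell is depolarized/hyperpolarized 1 s
#' before a 0.5 s split-spot flash; traces are trial-averaged, smoothed
#' with a Gaussian-weighted moving average (SD 10 ms, 50 ms window), and
#' the light-evoked amplitude (the signed deflection from baseline with the
#' largest magnitude) is plotted against the baseline potential; a straight
#' line gives the extrapolated reversal potential.
#' Current levels whose baseline is unstable (baseline SD above
#' `stability_sd_mv`) are excluded.
#'
#' @param cell a [subunit_cell()].
#' @param spot_diameter_um split-spot diameter.
#' @param currents_pa current levels (0 is added for the no-injection
#'   reference).
#' @param n_trials trials per current level.
#' @param seed integer seed.
#' @param stability_sd_mv baseline-stability exclusion threshold.
#' @return the [reversal_potential()] result plus the per-level table.
#' @export
current_injection_experiment <- function(cell, spot_diameter_um = 100,
                                         currents_pa = c(200, -200, 300,
                                                         -300, 400, -400),
                                         n_trials = 3, seed = 1,
                                         stability_sd_mv = 5) {
  currents_pa <- unique(c(0, currents_pa))
  canvas <- stim_canvas(2 * ceiling(spot_diameter_um / 2 +
                                      6 * cell$pooling$sigma_center_um),
                        pixel_size_um = 2.5, center_um = cell$center_um)
  spec <- spot_spec(center_um = cell$center_um,
                    diameter_um = spot_diameter_um, pattern = "halves",
                    contrast = if (cell$polarity == "OFF") -1 else 1,
                    mode = "flash", stim_duration_s = 0.5,
                    background_duration_s = 0.35, lead_background_s = 1)
  stim <- render_spot(spec, canvas, frame_rate_hz = 60)
  rate <- SIM_RATE_HZ
  rows <- lapply(seq_along(currents_pa), function(ci) {
    i_pa <- currents_pa[ci]
    trials <- simulate_voltage(cell, stim,
                               seed = child_seed(seed, paste0("inj", i_pa)),
                               injected_current_pa = i_pa,
                               n_trials = n_trials)
    if (n_trials == 1) trials <- list(trials)
    m <- rowMeans(vapply(trials, function(tr)
      gaussian_smooth(tr$samples_mv, sd_samples = 10, window_samples = 50),
      numeric(length(trials[[1]]))))
    i_on <- round(1 * rate) + 1
    bl_idx <- (i_on - round(0.2 * rate)):(i_on - 1)
    resp_idx <- i_on:min(i_on + round(0.65 * rate), length(m))
    bl <- mean(m[bl_idx])
    # signed deflection with the largest magnitude: beyond the reversal
    # potential the light response flips sign, and the signed amplitude
    # keeps the amplitude-versus-baseline relation linear through zero
    dev <- m[resp_idx] - bl
    data.frame(current_pa = i_pa,
               baseline_mv = bl,
               baseline_sd_mv = stats::sd(m[bl_idx]),
               peak_mv = dev[which.max(abs(dev))])
  })
  tab <- do.call(rbind, rows)
  use <- tab$baseline_sd_mv <= stability_sd_mv
  est <- if (sum(use) >= 3) {
    reversal_potential(tab$peak_mv[use], tab$baseline_mv[use])
  } else {
    list(e_rev_mv = NA_real_, se_mv = NA_real_, slope = NA_real_,
         flagged = TRUE)
  }
  est$table <- tab
  est$excluded <- sum(!use)
  est
}
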