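# End-to-end drivers: run the standard stimulus batteries on simulated
# cells, collect every index into one table per cell, and population-level
# statistics.  All stages derive their randomness from a single top-level
# seed via stable hashing of stage names, so results are reproducible and
# adding a stage never perturbs earlier stages' streams.

#' Patterned-spot battery: uniform, halves, quarters, checkerboard spots
#'
#' Renders the 1 Hz contrast-reversing uniform and patterned spots (4 s of
#' reversal preceded by 1 s background), simulates the cell's response,
#' forms baseline-independent cycle averages (first cycle dropped) and
#' computes the spatial nonlinearity index per pattern.
#'
#' @param cell a [subunit_cell()].
#' @param diameter_um spot diameter (the cell's local spot).
#' @param patterns patterned layouts to test.
#' @param n_trials trials per stimulus.
#' @param stim_duration_s reversal duration (4 s = 4 cycles at 1 Hz).
#' @param seed integer seed.
#' @return list with `cycles` (named list of 1-s cycle averages incl.
#'   `uniform`), `sni`, `sni_max`, and the sampling rate.
#' @export
measure_spot_battery <- function(cell, diameter_um,
                                 patterns = c("halves", "quarters",
                                              "check25"),
                                 n_trials = 3, stim_duration_s = 4,
                                 seed = 1) {
  canvas <- stim_canvas(spot_battery_canvas_um(cell, diameter_um),
                        pixel_size_um = 2.5, center_um = cell$center_um)
  contrast <- if (cell$polarity == "OFF") -1 else 1
  cycles <- lapply(stats::setNames(c("uniform", patterns),
                                   c("uniform", patterns)), function(pat) {
    spec <- spot_spec(center_um = cell$center_um, diameter_um = diameter_um,
                      pattern = pat, contrast = contrast, mode = "reversing",
                      reversal_hz = 1, stim_duration_s = stim_duration_s,
                      background_duration_s = 0.2, lead_background_s = 1)
    stim <- render_spot(spec, canvas, frame_rate_hz = 60)
    trials <- simulate_voltage(cell, stim,
                               seed = child_seed(seed, paste0("spot_", pat)),
                               n_trials = n_trials)
    if (n_trials == 1) trials <- list(trials)
    avg <- rowMeans(vapply(trials, function(tr) tr$samples_mv,
                           numeric(length(trials[[1]]))))
    cycle_average(avg, period_s = 1, rate_hz = SIM_RATE_HZ, start_s = 1,
                  drop_first = TRUE, demean = TRUE)
  })
  sni <- spatial_nonlinearity_index(cycles[patterns], cycles$uniform,
                                    SIM_RATE_HZ)
  list(cycles = cycles, sni = sni$sni, sni_max = sni$sni_max,
       rate_hz = SIM_RATE_HZ)
}

spot_battery_canvas_um <- function(cell, diameter_um) {
  need <- 2 * (3 * max(cell$pooling$sigma_center_um,
                       if (cell$pooling$k_surr > 0)
                         cell$pooling$sigma_surround_um else 0) +
                 cell$subunit_spacing_um)
  2.5 * ceiling(max(diameter_um + 20, need) / 2.5)
}

#' Flashed-spot contrast-step battery
#'
#' Flashes the local spot at preferred and non-preferred contrast
#' (0.5 s spot, 1 s background), averages baseline-subtracted responses
#' over trials, and computes the hyperpolarization index,
#' sustained-transient index and response latencies.
#'
#' @param cell a [subunit_cell()].
#' @param diameter_um spot diameter.
#' @param n_trials trials per contrast.
#' @param seed integer seed.
#' @return list with the index values and the averaged responses.
#' @export
measure_flash_battery <- function(cell, diameter_um, n_trials = 8,
                                  seed = 1) {
  canvas <- stim_canvas(spot_battery_canvas_um(cell, diameter_um),
                        pixel_size_um = 2.5, center_um = cell$center_um)
  pref <- if (cell$polarity == "OFF") -1 else 1
  resp <- lapply(stats::setNames(c(pref, -pref), c("preferred",
                                                   "nonpreferred")),
                 function(con) {
    spec <- spot_spec(center_um = cell$center_um, diameter_um = diameter_um,
                      pattern = "uniform", contrast = con, mode = "flash",
                      stim_duration_s = 0.5, background_duration_s = 0.5,
                      lead_background_s = 1)
    stim <- render_spot(spec, canvas, frame_rate_hz = 60)
    trials <- simulate_voltage(cell, stim,
                               seed = child_seed(seed, paste0("flash", con)),
                               n_trials = n_trials)
    if (n_trials == 1) trials <- list(trials)
    epochs <- data.frame(trial = seq_len(n_trials), onset_s = 1,
                         offset_s = 2, condition = "spot")
    epoch_average(trials, epochs)$spot
  })
  on_idx <- resp$preferred$time_s >= 0
  pref_resp <- resp$preferred$mean_mv[on_idx]
  hpi <- hyperpolarization_index(pref_resp,
                                 resp$nonpreferred$mean_mv[on_idx])
  sti <- sustained_transient_index(pref_resp, SIM_RATE_HZ)
  lat <- response_latency(pref_resp, resp$preferred$baseline_sd_mv,
                          SIM_RATE_HZ)
  list(hpi = hpi, sti = sti, onset_ms = lat$onset_ms,
       time_to_peak_ms = lat$time_to_peak_ms, responses = resp)
}

#' White-noise LN-model battery
#'
#' Renders the standard white-noise stimulus (binary 30 um checkerboard or
#' Gaussian full-field, with frozen test segments), simulates the cell,
#' conditions the trace (0.1 Hz high-pass detrend, binning at the stimulus
#' resolution), fits the LN model on the non-frozen data and scores the
#' trial-averaged frozen response.
#'
#' @param cell a [subunit_cell()].
#' @param layout `"checkerboard"` or `"fullfield"`.
#' @param duration_s stimulus duration.
#' @param update_rate_hz stimulus update rate (30 Hz).
#' @param square_size_um checkerboard square size (30 um).
#' @param seed integer seed.
#' @param ... forwarded to [crossvalidate_ln()] / [ln_fit()].
#' @return list with `model` (an `"ln_model"`), `r2`, `oni`, and for
#'   checkerboard stimuli the Gaussian RF fit.
#' @export
measure_ln_battery <- function(cell, layout = c("checkerboard", "fullfield"),
                               duration_s = 1200, update_rate_hz = 30,
                               square_size_um = 30, seed = 1, ...) {
  layout <- match.arg(layout)
  need <- 2 * (3 * max(cell$pooling$sigma_center_um,
                       if (cell$pooling$k_surr > 0)
                         cell$pooling$sigma_surround_um else 0) +
                 cell$subunit_spacing_um)
  if (layout == "checkerboard") {
    extent <- square_size_um * ceiling((need + 2 * square_size_um) /
                                         square_size_um)
    spec <- noise_spec(layout = "checkerboard",
                       square_size_um = square_size_um,
                       update_rate_hz = update_rate_hz,
                       distribution = "binary", duration_s = duration_s,
                       frozen_length_frames = 300,
                       frozen_period_frames = 1200,
                       extent_um = extent, center_um = cell$center_um,
                       seed = child_seed(seed, "stim"))
    stim <- render_checkerboard_noise(spec)
  } else {
    spec <- noise_spec(layout = "fullfield", update_rate_hz = update_rate_hz,
                       distribution = "gaussian", sd = 0.3,
                       duration_s = duration_s,
                       frozen_length_frames = 300,
                       frozen_period_frames = 900,
                       extent_um = 2.5 * ceiling(need / 2.5),
                       center_um = cell$center_um,
                       seed = child_seed(seed, "stim"))
    stim <- render_fullfield_noise(spec)
  }
  tr <- simulate_voltage(cell, stim, seed = child_seed(seed, "sim"))
  tr <- detrend_highpass(tr)
  resp <- bin_voltage_to_frames(
    tr, (seq_len(n_frames(stim)) - 1) / stim$frame_rate_hz)
  perf <- crossvalidate_ln(stim, resp, scheme = "frozen_repeats",
                           frozen = spec, ...)
  list(model = perf$model, r2 = perf$r2_mean,
       oni = output_nonlinearity_index(perf$model$outfn),
       rf = perf$model$rf, performance = perf, stim_spec = spec)
}

#' Split-spot prediction battery
#'
#' Runs the patterned-spot battery, predicts the patterned-spot response
#' from the uniform-spot cycle average, compares against the measured
#' pattern with the highest spatial nonlinearity index, and scores the
#' prediction accuracy.
#'
#' @param cell a [subunit_cell()].
#' @param diameter_um spot diameter.
#' @param seed integer seed.
#' @param ... forwarded to [measure_spot_battery()].
#' @return list with `accuracy`, `best_pattern`, `predicted`, `measured`,
#'   `battery`.
#' @export
measure_split_spot_prediction <- function(cell, diameter_um, seed = 1, ...) {
  bat <- measure_spot_battery(cell, diameter_um, seed = seed, ...)
  best <- names(which.max(bat$sni))
  pred <- predict_patterned_from_uniform(bat$cycles$uniform, bat$rate_hz)
  acc <- prediction_accuracy(bat$cycles[[best]], pred, bat$cycles$uniform)
  list(accuracy = acc, best_pattern = best, predicted = pred,
       measured = bat$cycles[[best]], battery = bat)
}

#' Run a full simulated experiment over a cell population
#'
#' Samples a cell population, runs the patterned-spot, flashed-spot and
#' white-noise batteries per cell, and assembles one row of indices per
#' cell.  Deterministic under `(config, seed)`.
#'
#' @param config list with entries `n_cells`, `population`
#'   (see [default_population_cfg()]), `noise_duration_s`,
#'   `spot_trials`, and logical toggles `run_flash`, `run_ln`,
#'   `run_prediction`.
#' @param seed top-level seed; per-cell and per-stage seeds are derived by
#'   stable hashing.
#' @return list with `cells`, `params` (ground truth) and `index_table`
#'   (data frame, one row per cell).
#' @export
run_experiment <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(
    list(n_cells = 5, population = default_population_cfg(),
         noise_duration_s = 300, spot_trials = 3,
         run_flash = TRUE, run_ln = TRUE, run_prediction = TRUE),
    config)
  cells <- sample_cell_population(cfg$population, cfg$n_cells,
                                  seed = child_seed(seed, "cells"))
  params <- attr(cells, "params")
  rows <- lapply(seq_along(cells), function(i) {
    cell <- cells[[i]]
    cseed <- child_seed(seed, paste0("cell", i))
    diam <- 10 * round(3 * cell$pooling$sigma_center_um / 10)
    bat <- measure_spot_battery(cell, diam, n_trials = cfg$spot_trials,
                                seed = child_seed(cseed, "spots"))
    row <- data.frame(cell = i, local_spot_diameter_um = diam,
                      theta = params$threshold[i],
                      sigma_center_um = params$sigma_center_um[i],
                      sni_halves = unname(bat$sni["halves"]),
                      sni_quarters = unname(bat$sni["quarters"]),
                      sni_check25 = unname(bat$sni["check25"]),
                      sni_max = bat$sni_max)
    if (cfg$run_flash) {
      fl <- measure_flash_battery(cell, diam, n_trials = cfg$spot_trials,
                                  seed = child_seed(cseed, "flash"))
      row$hpi <- fl$hpi; row$sti <- fl$sti
      row$onset_ms <- fl$onset_ms; row$time_to_peak_ms <- fl$time_to_peak_ms
    }
    if (cfg$run_ln) {
      ln <- measure_ln_battery(cell, "checkerboard",
                               duration_s = cfg$noise_duration_s,
                               seed = child_seed(cseed, "noise"))
      row$oni <- ln$oni
      row$r2_spatiotemporal <- ln$r2
      row$rf_diameter_um <- if (!is.null(ln$rf) && isTRUE(ln$rf$converged))
        ln$rf$diameter_1p5s_um else NA_real_
      tm <- temporal_filter_metrics(ln$model$filter$temporal,
                                    ln$model$frame_rate_hz)
      row$filter_peak_ms <- tm$time_to_peak_ms
      row$biphasic_index <- tm$biphasic_index
    }
    if (cfg$run_prediction) {
      pr <- measure_split_spot_prediction(cell, diam,
                                          n_trials = cfg$spot_trials,
                                          seed = child_seed(cseed, "spots"))
      row$prediction_accuracy <- pr$accuracy
    }
    row
  })
  list(cells = cells, params = params, index_table = do.call(rbind, rows))
}

#' Pearson correlations over an index table
#'
#' @param index_table data frame of per-cell indices.
#' @param pairs list of 2-element character vectors naming columns.
#' @param alpha significance level.
#' @return data frame with one row per pair: n, Pearson r, t-test p value
#'   and significance at `alpha`; pairs with fewer than 3 complete
#'   observations are reported as not computable.
#' @export
population_stats <- function(index_table, pairs, alpha = 0.05) {
  rows <- lapply(pairs, function(pr) {
    x <- index_table[[pr[1]]]; y <- index_table[[pr[2]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3)
      return(data.frame(x = pr[1], y = pr[2], n = sum(ok), r = NA_real_,
                        p = NA_real_, significant = NA))
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(x = pr[1], y = pr[2], n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value,
               significant = ct$p.value < alpha)
  })
  do.call(rbind, rows)
}

#' Write an index table as tidy CSV
#'
#' @param index_table data frame, one row per cell.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_index_table <- function(index_table, path) {
  utils::write.csv(index_table, path, row.names = FALSE)
  invisible(path)
}
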