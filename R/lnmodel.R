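# Linear-nonlinear (LN) model estimation for graded membrane potentials:
# response-weighted averaging (the graded-response analog of the
# spike-triggered average), space-time factorization by SVD, 2-D Gaussian
# receptive-field fits, the 40-bin output function, prediction and
# cross-validated explained variance.

#' Response-weighted average (spatiotemporal receptive field)
#'
#' For each lag l in `[0, window_s)` computes `sum_t r(t) s(t - l) / n`,
#' the cross-correlation between the binned response and the stimulus.  The
#' overall positive scale is arbitrary (it is absorbed when the factorized
#' filter components are normalized to unit Euclidean norm), so the sum is
#' divided by the number of contributing time bins.
#'
#' @param stim a [frame_sequence()].
#' @param response numeric vector, one (detrended) mean voltage per frame;
#'   `NA` entries are excluded as weights.
#' @param window_s filter window in seconds (2 s).
#' @param weights_mask optional logical vector: frames whose response may be
#'   used as a weight (e.g. `FALSE` inside frozen test segments).
#' @return an object of class `"strf"`: lag-by-pixel matrix plus geometry.
#' @export
response_weighted_average <- function(stim, response, window_s = 2,
                                      weights_mask = NULL) {
  stopifnot(inherits(stim, "frame_sequence"))
  d <- dim(stim$frames)
  Tn <- d[1]
  if (length(response) != Tn)
    stop("response length must equal the number of stimulus frames")
  L <- round(window_s * stim$frame_rate_hz)
  if (Tn <= L) stop("need more frames than the filter window")
  use <- !is.na(response)
  if (!is.null(weights_mask)) use <- use & weights_mask
  r <- ifelse(use, response, 0)
  if (all(r == 0) || stats::sd(r[use]) == 0)
    stop("degenerate weighting: response carries no signal")
  X <- matrix(stim$frames, nrow = Tn)
  strf <- matrix(0, L, ncol(X))
  for (l in 0:(L - 1)) {
    tt <- (l + 1):Tn
    strf[l + 1, ] <- crossprod(X[tt - l, , drop = FALSE], r[tt]) / sum(use)
  }
  structure(list(strf = strf, window_s = window_s,
                 frame_rate_hz = stim$frame_rate_hz,
                 n_rows = d[2], n_cols = d[3],
                 pixel_size_um = stim$pixel_size_um,
                 origin_um = stim$origin_um,
                 n_weights = sum(use)),
            class = "strf")
}

# 3-sigma-contour mask of a Gaussian RF fit over a pixel grid.
rf_contour_mask <- function(rf, geom, n_sigma = 3) {
  pc <- pixel_centers(geom)
  dx <- outer(rep(1, geom$n_rows), pc$x - rf$center_um[1])
  dy <- outer(pc$y - rf$center_um[2], rep(1, geom$n_cols))
  th <- rf$orientation_rad
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  (u / rf$sigma_x_um)^2 + (v / rf$sigma_y_um)^2 <= n_sigma^2
}

#' Factorize a spatiotemporal receptive field into space and time
#'
#' Crops a window (720 um to the side) around the peak-magnitude pixel,
#' optionally zeroes pixels outside the 3-sigma contour of a Gaussian RF
#' fit, and extracts the highest-ranked spatial and temporal components by
#' singular-value decomposition.  Both components have unit Euclidean norm;
#' the sign is fixed so that the spatial map is positive at the RF center,
#' which leaves the cell's polarity in the temporal kernel (first lobe
#' negative for OFF cells) and makes positive generator signals correspond
#' to preferred contrast.
#'
#' @param rwa an `"strf"` from [response_weighted_average()].
#' @param rf_fit optional [fit_gaussian_rf()] result for contour masking.
#' @param crop_um side length of the crop window.
#' @return an object of class `"st_filter"` with `spatial` (matrix),
#'   `temporal` (vector over lags), crop geometry, and the singular values.
#' @export
factorize_strf <- function(rwa, rf_fit = NULL, crop_um = 720) {
  stopifnot(inherits(rwa, "strf"))
  L <- nrow(rwa$strf)
  peak <- which.max(abs(rwa$strf))
  peak_px <- ((peak - 1) %/% L) + 1
  pr <- ((peak_px - 1) %% rwa$n_rows) + 1
  pcl <- ((peak_px - 1) %/% rwa$n_rows) + 1
  half_px <- max(1, round(crop_um / rwa$pixel_size_um / 2))
  clip_range <- function(center, half, n) {
    lo <- center - half; hi <- center + half
    if (lo < 1) { hi <- min(n, hi + (1 - lo)); lo <- 1 }
    if (hi > n) { lo <- max(1, lo - (hi - n)); hi <- n }
    lo:hi
  }
  rows <- clip_range(pr, half_px, rwa$n_rows)
  cols <- clip_range(pcl, half_px, rwa$n_cols)
  sub_idx <- as.vector(outer(rows, (cols - 1) * rwa$n_rows, "+"))
  M <- rwa$strf[, sub_idx, drop = FALSE]
  geom <- list(n_rows = length(rows), n_cols = length(cols),
               pixel_size_um = rwa$pixel_size_um,
               origin_um = c(rwa$origin_um[1] + (cols[1] - 1) * rwa$pixel_size_um,
                             rwa$origin_um[2] + (rows[1] - 1) * rwa$pixel_size_um))
  if (!is.null(rf_fit)) {
    mask <- rf_contour_mask(rf_fit, geom)
    M[, !as.vector(mask)] <- 0
  }
  sv <- svd(M)
  temporal <- sv$u[, 1]
  spatial_vec <- sv$v[, 1]
  # sign convention: spatial positive at the RF center / peak pixel
  ref <- if (!is.null(rf_fit)) {
    pc <- pixel_centers(geom)
    rr <- which.min(abs(pc$y - rf_fit$center_um[2]))
    cc <- which.min(abs(pc$x - rf_fit$center_um[1]))
    spatial_vec[(cc - 1) * geom$n_rows + rr]
  } else spatial_vec[which.max(abs(spatial_vec))]
  if (ref < 0) { spatial_vec <- -spatial_vec; temporal <- -temporal }
  structure(list(spatial = matrix(spatial_vec, geom$n_rows, geom$n_cols),
                 temporal = temporal, singular_values = sv$d,
                 n_rows = geom$n_rows, n_cols = geom$n_cols,
                 pixel_size_um = geom$pixel_size_um,
                 origin_um = geom$origin_um,
                 frame_rate_hz = rwa$frame_rate_hz,
                 window_s = rwa$window_s),
            class = "st_filter")
}

#' Fit a two-dimensional elliptical Gaussian to a spatial map
#'
#' Least-squares fit of `A exp(-q/2) + offset` with rotated elliptical
#' contours.  The receptive-field diameter is reported as the diameter of a
#' circle with the same area as the 1.5-sigma contour of the fit.
#'
#' @param spatial_map matrix of spatial weights.
#' @param geom geometry list (`n_rows`, `n_cols`, `pixel_size_um`,
#'   `origin_um`); defaults to a unit grid.
#' @param noise_sd optional noise level of the underlying receptive-field
#'   estimate; when given, the fit is flagged `rejected` if the mean map
#'   value within the 3-sigma contour is below `3 * noise_sd`.
#' @return an object of class `"gaussian_rf"`.
#' @export
fit_gaussian_rf <- function(spatial_map, geom = NULL, noise_sd = NULL) {
  if (is.null(geom))
    geom <- list(n_rows = nrow(spatial_map), n_cols = ncol(spatial_map),
                 pixel_size_um = 1, origin_um = c(0, 0))
  pc <- pixel_centers(geom)
  dx <- outer(rep(1, geom$n_rows), pc$x)
  dy <- outer(pc$y, rep(1, geom$n_cols))
  z <- spatial_map
  # moment-based initialization on the dominant-sign lobe
  pk <- which.max(abs(z))
  sgn <- sign(z[pk])
  zp <- pmax(sgn * z, 0)
  w <- zp / sum(zp)
  x0 <- sum(w * dx); y0 <- sum(w * dy)
  sx <- sqrt(max(sum(w * (dx - x0)^2), (geom$pixel_size_um / 4)^2))
  sy <- sqrt(max(sum(w * (dy - y0)^2), (geom$pixel_size_um / 4)^2))
  par0 <- c(A = sgn * max(abs(z)), x0 = x0, y0 = y0,
            lsx = log(sx), lsy = log(sy), th = 0, off = stats::median(z))
  model <- function(p) {
    u <- cos(p[6]) * (dx - p[2]) + sin(p[6]) * (dy - p[3])
    v <- -sin(p[6]) * (dx - p[2]) + cos(p[6]) * (dy - p[3])
    p[1] * exp(-0.5 * ((u / exp(p[4]))^2 + (v / exp(p[5]))^2)) + p[7]
  }
  fit <- try(stats::optim(par0, function(p) sum((model(p) - z)^2),
                          method = "BFGS",
                          control = list(maxit = 2000, reltol = 1e-10)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(converged = FALSE, rejected = TRUE),
                     class = "gaussian_rf"))
  }
  p <- fit$par
  rf <- structure(list(
    center_um = c(p[["x0"]], p[["y0"]]),
    sigma_x_um = exp(p[["lsx"]]), sigma_y_um = exp(p[["lsy"]]),
    orientation_rad = p[["th"]] %% pi,
    amplitude = p[["A"]], offset = p[["off"]],
    diameter_1p5s_um = 2 * 1.5 * sqrt(exp(p[["lsx"]]) * exp(p[["lsy"]])),
    converged = fit$convergence == 0, rejected = FALSE,
    rss = fit$value), class = "gaussian_rf")
  if (!is.null(noise_sd)) {
    mask <- rf_contour_mask(rf, geom)
    if (!any(mask) || mean(z[mask]) * sign(rf$amplitude) < 3 * noise_sd)
      rf$rejected <- TRUE
  }
  rf
}

#' @export
print.gaussian_rf <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<gaussian_rf> fit did not converge (flagged)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<gaussian_rf> center (%.1f, %.1f) um, sigma (%.1f, %.1f) um, 1.5-sigma diameter %.1f um%s\n",
    x$center_um[1], x$center_um[2], x$sigma_x_um, x$sigma_y_um,
    x$diameter_1p5s_um, if (x$rejected) " [rejected: noisy RF]" else ""))
  invisible(x)
}

# Match the filter's pixel grid into a stimulus, by world coordinates.
filter_stim_indices <- function(filt, stim) {
  if (abs(filt$pixel_size_um - stim$pixel_size_um) > 1e-9)
    stop(sprintf(
      "geometry mismatch: filter grid %.3g um/px vs stimulus %.3g um/px",
      filt$pixel_size_um, stim$pixel_size_um))
  pcf <- pixel_centers(filt)
  pcs <- pixel_centers(stim)
  cc <- match(round(pcf$x, 6), round(pcs$x, 6))
  rr <- match(round(pcf$y, 6), round(pcs$y, 6))
  if (anyNA(cc) || anyNA(rr))
    stop(sprintf(
      "geometry mismatch: filter window [%.1f, %.1f]x[%.1f, %.1f] um not inside stimulus",
      pcf$x[1], pcf$x[length(pcf$x)], pcf$y[1], pcf$y[length(pcf$y)]))
  H <- dim(stim$frames)[2]
  as.vector(outer(rr, (cc - 1) * H, "+"))
}

#' Generator signal of an LN model
#'
#' Applies the spatial filter to each frame (scalar product with the pixel
#' contrasts) and convolves the result causally with the temporal kernel.
#' The first `window_s` of output, where the filter history is incomplete,
#' is returned as `NA`.
#'
#' @param filt an `"st_filter"` from [factorize_strf()].
#' @param stim a [frame_sequence()] on the same pixel grid.
#' @return numeric generator signal, one value per frame.
#' @export
compute_generator_signal <- function(filt, stim) {
  stopifnot(inherits(filt, "st_filter"), inherits(stim, "frame_sequence"))
  idx <- filter_stim_indices(filt, stim)
  X <- matrix(stim$frames, nrow = dim(stim$frames)[1])
  g_sp <- as.vector(X[, idx, drop = FALSE] %*% as.vector(filt$spatial))
  as.vector(stats::filter(g_sp, filt$temporal, method = "convolution",
                          sides = 1))
}

#' Estimate the output function (static nonlinearity)
#'
#' Bins the generator signal into `n_bins` bins with equal numbers of data
#' points and averages both the generator signal and the membrane potential
#' within each bin.
#'
#' @param generator generator signal (NA entries are dropped).
#' @param response corresponding binned voltage.
#' @param n_bins number of equal-occupancy bins (40).
#' @return an object of class `"output_function"`: data frame with columns
#'   `generator`, `voltage`, `count`.
#' @export
estimate_output_function <- function(generator, response, n_bins = 40) {
  ok <- !is.na(generator) & !is.na(response)
  g <- generator[ok]; r <- response[ok]
  if (length(g) < 10 * n_bins)
    stop(sprintf("need at least %d valid frames for %d bins (have %d)",
                 10 * n_bins, n_bins, length(g)))
  o <- order(g)
  edges <- round(seq(0, length(g), length.out = n_bins + 1))
  bin <- rep(seq_len(n_bins), diff(edges))
  gs <- g[o]; rs <- r[o]
  out <- data.frame(
    generator = as.vector(tapply(gs, bin, mean)),
    voltage = as.vector(tapply(rs, bin, mean)),
    count = as.vector(table(bin)))
  structure(out, class = c("output_function", "data.frame"))
}

#' Evaluate an output function with linear inter-/extrapolation
#'
#' Piecewise-linear interpolation through the bin means; beyond the end
#' bins, linear extrapolation with the slope of the outermost two bins.
#'
#' @param outfn an `"output_function"`.
#' @param x generator values.
#' @return predicted voltage values.
#' @export
interpolate_output <- function(outfn, x) {
  g <- outfn$generator; v <- outfn$voltage
  n <- length(g)
  y <- stats::approx(g, v, xout = x, rule = 2)$y
  lo <- !is.na(x) & x < g[1]
  hi <- !is.na(x) & x > g[n]
  y[lo] <- v[1] + (x[lo] - g[1]) * (v[2] - v[1]) / (g[2] - g[1])
  y[hi] <- v[n] + (x[hi] - g[n]) * (v[n] - v[n - 1]) / (g[n] - g[n - 1])
  y[is.na(x)] <- NA_real_
  y
}

#' Explained variance as squared Pearson correlation
#'
#' @param pred,measured equal-length vectors; NA pairs dropped.
#' @return R^2, or `NA` when either input is constant (undefined rather
#'   than zero).
#' @export
evaluate_r2 <- function(pred, measured) {
  ok <- !is.na(pred) & !is.na(measured)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(pred[ok]) == 0 || stats::sd(measured[ok]) == 0)
    return(NA_real_)
  stats::cor(pred[ok], measured[ok])^2
}

#' Fit a linear-nonlinear model to a white-noise recording
#'
#' The standard estimation sequence for graded responses: response-weighted
#' average over a 2 s window, SVD factorization within a 720 um crop window,
#' a 2-D Gaussian fit to the spatial component, re-factorization with pixels
#' outside the 3-sigma contour set to zero, and the 40-bin output function.
#' For spatially uniform (single-pixel) stimuli the model reduces to a
#' temporal filter plus output function.
#'
#' @param stim a [frame_sequence()].
#' @param response numeric vector of binned (detrended) voltage per frame,
#'   or a [voltage_trace()] which is then detrended and binned.
#' @param window_s filter window (2 s).
#' @param crop_um crop window side (720 um).
#' @param n_bins output-function bins (40).
#' @param weights_mask optional logical mask of frames usable for fitting
#'   (e.g. excluding frozen test segments).
#' @param noise_check estimate the receptive-field noise level from lags
#'   `window_s .. 2 window_s` and flag noisy RFs (doubles the RWA cost).
#' @param rf_fixed optional `"gaussian_rf"`: reuse this contour for masking
#'   instead of refitting the Gaussian (used by the held-out scheme).
#' @return an object of class `"ln_model"`.
#' @export
ln_fit <- function(stim, response, window_s = 2, crop_um = 720, n_bins = 40,
                   weights_mask = NULL, noise_check = FALSE,
                   rf_fixed = NULL) {
  stopifnot(inherits(stim, "frame_sequence"))
  if (inherits(response, "voltage_trace")) {
    tr <- detrend_highpass(response)
    response <- bin_voltage_to_frames(
      tr, (seq_len(n_frames(stim)) - 1) / stim$frame_rate_hz)
  }
  P <- prod(dim(stim$frames)[2:3])
  win <- if (noise_check && P > 1) 2 * window_s else window_s
  rwa_all <- response_weighted_average(stim, response, win, weights_mask)
  L <- round(window_s * stim$frame_rate_hz)
  rwa <- rwa_all
  rwa$strf <- rwa_all$strf[seq_len(L), , drop = FALSE]
  rwa$window_s <- window_s
  noise_sd <- if (noise_check && P > 1)
    stats::sd(rwa_all$strf[(L + 1):nrow(rwa_all$strf), ]) else NULL
  if (P == 1) {
    k <- rwa$strf[, 1]
    k <- k / sqrt(sum(k^2))
    filt <- structure(list(spatial = matrix(1, 1, 1), temporal = k,
                           singular_values = NA_real_, n_rows = 1, n_cols = 1,
                           pixel_size_um = stim$pixel_size_um,
                           origin_um = stim$origin_um,
                           frame_rate_hz = stim$frame_rate_hz,
                           window_s = window_s),
                      class = "st_filter")
    rf <- NULL
  } else if (!is.null(rf_fixed)) {
    rf <- rf_fixed
    filt <- factorize_strf(rwa, rf_fit = if (isTRUE(rf$converged)) rf,
                           crop_um = crop_um)
  } else {
    f1 <- factorize_strf(rwa, rf_fit = NULL, crop_um = crop_um)
    geom <- list(n_rows = f1$n_rows, n_cols = f1$n_cols,
                 pixel_size_um = f1$pixel_size_um, origin_um = f1$origin_um)
    rf <- fit_gaussian_rf(f1$spatial, geom, noise_sd = noise_sd)
    filt <- if (isTRUE(rf$converged))
      factorize_strf(rwa, rf_fit = rf, crop_um = crop_um) else f1
  }
  gen <- compute_generator_signal(filt, stim)
  gen_fit <- gen
  if (!is.null(weights_mask)) gen_fit[!weights_mask] <- NA
  gen_fit[is.na(response)] <- NA
  outfn <- estimate_output_function(gen_fit, response, n_bins)
  pred <- interpolate_output(outfn, gen_fit)
  structure(list(filter = filt, rf = rf, outfn = outfn, rwa = rwa,
                 generator = gen, response = response,
                 r2_train = evaluate_r2(pred, response),
                 frame_rate_hz = stim$frame_rate_hz,
                 window_s = window_s, n_bins = n_bins),
            class = "ln_model")
}

#' @export
print.ln_model <- function(x, ...) {
  tm <- temporal_filter_metrics(x$filter$temporal, x$frame_rate_hz)
  cat(sprintf("<ln_model> %s filter, %d lags at %g Hz\n",
              if (x$filter$n_rows * x$filter$n_cols > 1)
                sprintf("%d x %d px spatial x temporal",
                        x$filter$n_rows, x$filter$n_cols)
              else "temporal-only",
              length(x$filter$temporal), x$frame_rate_hz))
  cat(sprintf("  polarity %s, time-to-peak %.1f ms, biphasic index %.2f\n",
              tm$polarity, tm$time_to_peak_ms, tm$biphasic_index))
  if (!is.null(x$rf) && isTRUE(x$rf$converged))
    cat(sprintf("  RF diameter (1.5 sigma) %.1f um%s\n", x$rf$diameter_1p5s_um,
                if (x$rf$rejected) " [rejected: noisy]" else ""))
  cat(sprintf("  output function: %d bins; training R^2 = %.3f\n",
              nrow(x$outfn), x$r2_train))
  invisible(x)
}

#' @export
summary.ln_model <- function(object, ...) {
  c(coef(object), r2_train = object$r2_train)
}

#' @export
coef.ln_model <- function(object, ...) {
  tm <- temporal_filter_metrics(object$filter$temporal, object$frame_rate_hz)
  out <- c(time_to_peak_ms = tm$time_to_peak_ms,
           biphasic_index = tm$biphasic_index,
           oni = output_nonlinearity_index(object$outfn))
  if (!is.null(object$rf) && isTRUE(object$rf$converged))
    out <- c(out, rf_diameter_um = unname(object$rf$diameter_1p5s_um),
             rf_sigma_x_um = unname(object$rf$sigma_x_um),
             rf_sigma_y_um = unname(object$rf$sigma_y_um))
  out
}

#' Predict the voltage response to a stimulus from a fitted LN model
#'
#' @param object an `"ln_model"`.
#' @param stim a [frame_sequence()] on the model's pixel grid.
#' @param ... unused.
#' @return predicted voltage per frame (NA during the filter warm-up).
#' @export
predict.ln_model <- function(object, stim, ...) {
  gen <- compute_generator_signal(object$filter, stim)
  interpolate_output(object$outfn, gen)
}

#' @export
residuals.ln_model <- function(object, ...) {
  object$response - interpolate_output(object$outfn, object$generator)
}

#' @export
plot.ln_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (x$filter$n_rows * x$filter$n_cols > 1) {
    graphics::image(t(x$filter$spatial), main = "spatial filter",
                    col = grDevices::hcl.colors(64, "Blue-Red 2"),
                    axes = FALSE)
  } else {
    graphics::plot.new(); graphics::title("full-field (no spatial filter)")
  }
  lag_ms <- (seq_along(x$filter$temporal) - 1) * 1000 / x$frame_rate_hz
  graphics::plot(-lag_ms, x$filter$temporal, type = "l",
                 xlab = "time before response (ms)", ylab = "weight",
                 main = "temporal filter")
  graphics::abline(h = 0, lty = 3)
  graphics::plot(x$outfn$generator, x$outfn$voltage, pch = 16, cex = 0.6,
                 xlab = "generator signal", ylab = "voltage (mV)",
                 main = "output function")
  invisible(x)
}

#' Sub-bin peak latency and biphasic index of a temporal filter
#'
#' The first peak is the polarity-defining extremum (minimum for OFF,
#' maximum for ON); its latency is refined by a quadratic through the
#' extremum and its two neighbors (exact for a sampled parabola).  The
#' biphasic index is the ratio of the absolute values of the opposite-sign
#' second peak (at longer latency) and the first peak.
#'
#' @param temporal temporal kernel over lags (lag 0 first).
#' @param frame_rate_hz lag sampling rate.
#' @param polarity `"ON"`, `"OFF"` or `NULL` (inferred from the dominant
#'   extremum).
#' @return list with `time_to_peak_ms`, `biphasic_index`, `polarity`, and
#'   `boundary_flag` (TRUE when the extremum sits at the kernel boundary).
#' @export
temporal_filter_metrics <- function(temporal, frame_rate_hz,
                                    polarity = NULL) {
  k <- as.numeric(temporal)
  n <- length(k)
  if (is.null(polarity))
    polarity <- if (k[which.max(abs(k))] >= 0) "ON" else "OFF"
  s <- if (polarity == "ON") 1 else -1
  i1 <- which.max(s * k)
  boundary <- i1 == 1 || i1 == n
  delta <- 0
  if (!boundary) {
    y <- k[(i1 - 1):(i1 + 1)]
    denom <- y[1] - 2 * y[2] + y[3]
    if (denom != 0) delta <- 0.5 * (y[1] - y[3]) / denom
  }
  dt_ms <- 1000 / frame_rate_hz
  after <- if (i1 < n) k[(i1 + 1):n] else numeric(0)
  second <- if (length(after)) max(0, -s * after) else 0
  list(time_to_peak_ms = (i1 - 1 + delta) * dt_ms,
       biphasic_index = second / abs(k[i1]),
       polarity = polarity, boundary_flag = boundary)
}

#' Cross-validated LN-model performance
#'
#' Two schemes.  `"heldout_segments"`: segments of consecutive frames are
#' drawn at random; for each one the model is refit on the remaining data
#' (the Gaussian contour mask from the full fit is reused) and the segment's
#' response is predicted; reported as the mean R^2 over segments.
#' `"frozen_repeats"`: the stimulus contains a frozen segment repeated
#' throughout the run; the model is fit on the non-repeated frames only and
#' scored against the trial-averaged response to the frozen segment.
#'
#' @param stim a [frame_sequence()].
#' @param response binned voltage per frame.
#' @param scheme `"heldout_segments"` or `"frozen_repeats"`.
#' @param n_segments,segment_frames held-out scheme: number and length of
#'   test segments (200 x 300).
#' @param frozen for the frozen scheme, the schedule as returned by
#'   `frozen_schedule` (list with `frozen`, `within`), or a `noise_spec`.
#' @param seed seed for segment placement.
#' @param ... forwarded to [ln_fit()].
#' @return an object of class `"ln_performance"` with `r2_mean` and
#'   per-segment values.
#' @export
crossvalidate_ln <- function(stim, response,
                             scheme = c("frozen_repeats", "heldout_segments"),
                             n_segments = 200, segment_frames = 300,
                             frozen = NULL, seed = 1, ...) {
  scheme <- match.arg(scheme)
  Tn <- n_frames(stim)
  if (scheme == "frozen_repeats") {
    if (inherits(frozen, "noise_spec"))
      frozen <- frozen_schedule(Tn, frozen$frozen_length_frames,
                                frozen$frozen_period_frames)
    if (is.null(frozen)) stop("frozen schedule required for frozen_repeats")
    fr <- frozen$frozen
    model <- ln_fit(stim, response, weights_mask = !fr, ...)
    gen <- model$generator
    pred_all <- interpolate_output(model$outfn, gen)
    ins <- cumsum(frozen$within == 1 & fr) * fr
    full_len <- max(frozen$within)
    ids <- setdiff(unique(ins), 0)
    keep <- ids[vapply(ids, function(i) sum(ins == i) == full_len,
                       logical(1))]
    if (length(keep) < 2) stop("need at least two complete frozen insertions")
    meas <- rowMeans(vapply(keep, function(i) response[ins == i],
                            numeric(full_len)))
    pred <- rowMeans(vapply(keep, function(i) pred_all[ins == i],
                            numeric(full_len)), na.rm = TRUE)
    r2 <- evaluate_r2(pred, meas)
    return(structure(list(r2_mean = r2, r2_segments = r2, scheme = scheme,
                          n_trials = length(keep), model = model,
                          predicted = pred, measured = meas),
                     class = "ln_performance"))
  }
  # held-out segments
  full <- ln_fit(stim, response, ...)
  with_seed(child_seed(seed, "heldout"),
            starts <- sample.int(Tn - segment_frames + 1, n_segments,
                                 replace = n_segments > Tn - segment_frames))
  r2s <- vapply(starts, function(a) {
    b <- min(a + segment_frames - 1, Tn)
    mask <- rep(TRUE, Tn); mask[a:b] <- FALSE
    m <- ln_fit(stim, response, weights_mask = mask, rf_fixed = full$rf, ...)
    pred <- interpolate_output(m$outfn, m$generator[a:b])
    evaluate_r2(pred, response[a:b])
  }, numeric(1))
  structure(list(r2_mean = mean(r2s, na.rm = TRUE), r2_segments = r2s,
                 scheme = scheme, model = full),
            class = "ln_performance")
}

#' @export
print.ln_performance <- function(x, ...) {
  cat(sprintf("<ln_performance> %s: mean R^2 = %.3f (%d segments/trials)\n",
              x$scheme, x$r2_mean, length(x$r2_segments)))
  invisible(x)
}

#' Output function and LN prediction under a natural(istic) movie
#'
#' Keeps the spatiotemporal filter estimated under white noise, filters the
#' movie with it, and (a) predicts the movie response through the
#' white-noise output function (scored by R^2 against the trial-averaged
#' response), (b) re-derives a movie-specific output function from the
#' relation between the filtered movie and the measured response, from
#' which the movie output-nonlinearity index can be computed.
#'
#' @param model an `"ln_model"` fitted on white noise.
#' @param movie a [frame_sequence()] on the model's pixel grid.
#' @param movie_response trial-averaged binned voltage per movie frame.
#' @param n_bins bins of the movie output function (40).
#' @return list with `r2`, `prediction`, `generator` and `outfn_movie`.
#' @export
movie_nonlinearity <- function(model, movie, movie_response, n_bins = 40) {
  stopifnot(inherits(model, "ln_model"))
  gen <- compute_generator_signal(model$filter, movie)
  pred <- interpolate_output(model$outfn, gen)
  list(r2 = evaluate_r2(pred, movie_response),
       prediction = pred, generator = gen,
       outfn_movie = estimate_output_function(gen, movie_response, n_bins))
}
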