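# white-noise frame sequence on an abstract unit grid
unit_noise <- function(Tn, H, W, seed = 1, rate = 30) {
  set.seed(seed)
  frame_sequence(array(sample(c(-1, 1), Tn * H * W, replace = TRUE),
                       c(Tn, H, W)),
                 pixel_size_um = 10, frame_rate_hz = rate)
}

test_that("RWA recovers a delta and vanishes for unrelated responses", {
  st <- unit_noise(4000, 4, 4, seed = 2)
  X <- matrix(st$frames, nrow = 4000)
  # response = contrast of pixel (2,3) at zero lag
  px <- (3 - 1) * 4 + 2
  rwa <- response_weighted_average(st, X[, px], window_s = 0.5)
  expect_equal(which.max(abs(rwa$strf)), (px - 1) * nrow(rwa$strf) + 1)
  expect_gt(abs(rwa$strf[1, px]) / max(abs(rwa$strf[, -px])), 5)
  # independent response: everything shrinks as 1/sqrt(T)
  set.seed(3)
  rwa0 <- response_weighted_average(st, rnorm(4000), window_s = 0.5)
  expect_lt(max(abs(rwa0$strf)), 6 / sqrt(4000))
  expect_error(response_weighted_average(st, rep(0, 4000)), "degenerate")
})

test_that("SVD factorization is exact for separable input and optimal rank 1", {
  set.seed(4)
  S <- exp(-((1:8 - 4.5)^2 %o% rep(1, 8) + rep(1, 8) %o% (1:8 - 4.5)^2) / 8)
  K <- sin(1:20 / 3) * exp(-(1:20) / 8)
  M <- K %o% as.vector(S)
  rwa <- structure(list(strf = M, window_s = 20 / 30, frame_rate_hz = 30,
                        n_rows = 8, n_cols = 8, pixel_size_um = 10,
                        origin_um = c(0, 0)), class = "strf")
  f <- factorize_strf(rwa, crop_um = 800)
  cos_sp <- abs(sum(f$spatial * S)) / sqrt(sum(S^2))
  cos_tm <- abs(sum(f$temporal * K)) / sqrt(sum(K^2))
  expect_gt(cos_sp, 0.999)
  expect_gt(cos_tm, 0.999)
  # unit norms
  expect_equal(sum(f$spatial^2), 1, tolerance = 1e-12)
  expect_equal(sum(f$temporal^2), 1, tolerance = 1e-12)

  # with noise: rank-1 residual bounded by the noise energy
  N <- matrix(rnorm(length(M), 0, 0.01), nrow(M))
  rwa$strf <- M + N
  fn <- factorize_strf(rwa, crop_um = 800)
  recon <- fn$singular_values[1] * fn$temporal %o% as.vector(fn$spatial)
  expect_lte(sum((rwa$strf - recon)^2), sum(N^2))

  # brute-force oracle: alternating least squares from random starts finds
  # no better rank-1 approximation than the SVD truncation
  best <- Inf
  for (s in 1:5) {
    set.seed(s)
    v <- rnorm(ncol(M)); v <- v / sqrt(sum(v^2))
    for (i in 1:200) {
      u <- rwa$strf %*% v
      v <- crossprod(rwa$strf, u); v <- v / sqrt(sum(v^2))
    }
    u <- rwa$strf %*% v
    best <- min(best, sum((rwa$strf - u %*% t(v))^2))
  }
  expect_lt(abs(best - sum((rwa$strf - recon)^2)) / sum(rwa$strf^2), 1e-9)
})

test_that("Gaussian RF fit: analytic diameter, rejection of noise maps", {
  geom <- list(n_rows = 21, n_cols = 21, pixel_size_um = 10,
               origin_um = c(0, 0))
  pc <- bipolarLN:::pixel_centers(geom)
  z <- exp(-(outer(rep(1, 21), (pc$x - 105)^2) +
               outer((pc$y - 105)^2, rep(1, 21))) / (2 * 40^2))
  rf <- fit_gaussian_rf(z, geom)
  expect_true(rf$converged)
  # isotropic sigma = 40 -> 1.5-sigma equal-area diameter = 120
  expect_equal(rf$diameter_1p5s_um, 120, tolerance = 0.01)
  expect_equal(rf$center_um, c(105, 105), tolerance = 0.5)
  expect_false(rf$rejected)
  # pure-noise map is flagged by the 3-sigma signal criterion
  set.seed(7)
  zn <- matrix(rnorm(441, 0, 0.1), 21, 21)
  rfn <- fit_gaussian_rf(zn, geom, noise_sd = 0.1)
  expect_true(rfn$rejected)
})

test_that("generator signal identities hold", {
  st <- unit_noise(3000, 3, 3, seed = 5)
  filt <- structure(list(spatial = matrix(1 / 3, 3, 3),
                         temporal = c(0.8, 0.5, 0.2, 0.1),
                         n_rows = 3, n_cols = 3, pixel_size_um = 10,
                         origin_um = c(0, 0), frame_rate_hz = 30,
                         window_s = 4 / 30), class = "st_filter")
  gen <- compute_generator_signal(filt, st)
  expect_true(all(is.na(gen[1:3])))
  # static stimulus equal to the spatial map: generator = sum(k) * |map|^2
  stat <- st
  stat$frames <- array(rep(as.vector(t(filt$spatial)), each = 30),
                       c(30, 3, 3))
  for (f in 1:30) stat$frames[f, , ] <- filt$spatial
  gs <- compute_generator_signal(filt, stat)
  expect_equal(gs[10], sum(filt$temporal) * sum(filt$spatial^2),
               tolerance = 1e-12)
  # white noise: generator mean ~ 0
  expect_lt(abs(mean(gen, na.rm = TRUE)), 0.05)
  # geometry mismatch errors
  bad <- unit_noise(100, 3, 3, seed = 1)
  bad$pixel_size_um <- 7
  expect_error(compute_generator_signal(filt, bad), "geometry mismatch")
})

test_that("output function: equal occupancy and canonical shapes", {
  set.seed(8)
  g <- rnorm(4000)
  ofn <- estimate_output_function(g, g)
  expect_equal(nrow(ofn), 40)
  expect_true(all(abs(ofn$count - 100) <= 1))
  expect_true(all(diff(ofn$generator) > 0))
  # identity response lies on the identity line
  expect_equal(ofn$voltage, ofn$generator, tolerance = 1e-12)
  # rectifier: left-half bin means ~ 0
  ofr <- estimate_output_function(g, pmax(g, 0))
  expect_lt(max(abs(ofr$voltage[ofr$generator < -0.2])), 1e-12)
  # noisy linear response: fitted overall slope ~ 1
  ofl <- estimate_output_function(g, g + rnorm(4000, 0, 0.3))
  sl <- stats::coef(stats::lm(voltage ~ generator, ofl))[2]
  expect_equal(unname(sl), 1, tolerance = 0.05)
  expect_error(estimate_output_function(g[1:100], g[1:100]), "valid frames")
})

test_that("interpolation extrapolates with the end-segment slopes", {
  ofn <- structure(data.frame(generator = c(-2, -1, 0, 1, 2),
                              voltage = c(0, 0, 0, 2, 4),
                              count = rep(10, 5)),
                   class = c("output_function", "data.frame"))
  expect_equal(interpolate_output(ofn, c(-5, 0.5, 3)), c(0, 1, 6))
})

test_that("R2 is the squared correlation with documented edge cases", {
  x <- sin(1:100)
  expect_equal(evaluate_r2(x, x), 1)
  expect_equal(evaluate_r2(-x, x), 1)  # sign-blind by definition
  expect_true(is.na(evaluate_r2(rep(1, 100), x)))
})

test_that("temporal filter metrics: exact parabola peak, biphasic bounds", {
  # sampled parabola peaking between bins: quadratic recovery is exact
  tt <- 0:10
  y <- -(tt - 4.3)^2 + 20
  tm <- temporal_filter_metrics(y, 1000)
  expect_equal(tm$time_to_peak_ms, 4.3, tolerance = 1e-10)
  # symmetric biphasic kernel with equal lobes -> index 1
  k <- c(0, 1, 2, 1, 0, -1, -2, -1, 0)
  tm2 <- temporal_filter_metrics(k, 1000, polarity = "ON")
  expect_equal(tm2$biphasic_index, 1)
  # monophasic kernel -> index ~ 0
  k3 <- exp(-((0:20) - 5)^2 / 4)
  expect_equal(temporal_filter_metrics(k3, 1000)$biphasic_index, 0)
  # boundary extremum flagged
  expect_true(temporal_filter_metrics(10:1, 1000,
                                      polarity = "ON")$boundary_flag)
})

test_that("LN fit recovers a simulated linear cell and is scale invariant", {
  cell <- linear_cell()
  st <- small_noise(240, seed = 31)
  tr <- simulate_voltage(cell, st, seed = 32)
  resp <- bin_voltage_to_frames(
    detrend_highpass(tr), (seq_len(n_frames(st)) - 1) / st$frame_rate_hz)
  m <- ln_fit(st, resp)
  # ground-truth comparison: RF diameter near 3 sigma of the pooling
  expect_equal(m$rf$diameter_1p5s_um, 3 * cell$pooling$sigma_center_um,
               tolerance = 0.10)
  tm <- temporal_filter_metrics(m$filter$temporal, m$frame_rate_hz)
  expect_identical(tm$polarity, "OFF")
  # generator correlates with the noiseless drive
  drive <- bipolarLN:::compute_drive(cell, st)
  drive_f <- bin_voltage_to_frames(
    voltage_trace(drive, 1000), (seq_len(n_frames(st)) - 1) / st$frame_rate_hz)
  ok <- !is.na(m$generator)
  expect_gt(stats::cor(m$generator[ok], drive_f[ok]), 0.95)
  # scale invariance: scaling the response leaves filter and R2 unchanged
  m2 <- ln_fit(st, 3.7 * resp)
  expect_equal(m2$filter$temporal, m$filter$temporal, tolerance = 1e-9)
  expect_equal(m2$filter$spatial, m$filter$spatial, tolerance = 1e-9)
  expect_equal(m2$r2_train, m$r2_train, tolerance = 1e-9)
  expect_equal(m2$outfn$voltage, 3.7 * m$outfn$voltage, tolerance = 1e-9)
})

test_that("cross-validation schemes agree on a deterministic cell", {
  cell <- linear_cell()
  spec <- noise_spec(duration_s = 240, extent_um = 240, seed = 41,
                     frozen_length_frames = 300, frozen_period_frames = 1200)
  st <- render_checkerboard_noise(spec)
  tr <- simulate_voltage(cell, st, seed = 42)
  resp <- bin_voltage_to_frames(
    detrend_highpass(tr), (seq_len(n_frames(st)) - 1) / st$frame_rate_hz)
  frozen <- crossvalidate_ln(st, resp, "frozen_repeats", frozen = spec)
  held <- crossvalidate_ln(st, resp, "heldout_segments", n_segments = 12,
                           segment_frames = 300, seed = 43)
  expect_gt(frozen$r2_mean, 0.9)
  expect_lt(abs(frozen$r2_mean - held$r2_mean), 0.05)
  # shuffled response carries no predictable signal
  set.seed(44)
  shuf <- crossvalidate_ln(st, sample(resp), "heldout_segments",
                           n_segments = 6, segment_frames = 300, seed = 45)
  expect_lt(abs(shuf$r2_mean), 0.1)
})

test_that("movie analysis transfers the white-noise filter", {
  cell <- linear_cell()
  # white noise at the movie frame rate, as in the matched-rate protocol
  st <- render_checkerboard_noise(noise_spec(duration_s = 240,
                                             extent_um = 240,
                                             update_rate_hz = 25, seed = 51))
  tr <- simulate_voltage(cell, st, seed = 52)
  resp <- bin_voltage_to_frames(
    detrend_highpass(tr), (seq_len(n_frames(st)) - 1) / st$frame_rate_hz)
  m <- ln_fit(st, resp)
  mv <- render_movie_surrogate(duration_s = 60, frame_rate_hz = 25,
                               extent_um = 240, pixel_size_um = 30,
                               seed = 53)
  mtr <- simulate_voltage(cell, mv, seed = 54)
  mresp <- bin_voltage_to_frames(
    detrend_highpass(mtr), (seq_len(n_frames(mv)) - 1) / mv$frame_rate_hz)
  res <- movie_nonlinearity(m, mv, mresp)
  expect_gt(res$r2, 0.9)
  # linear cell: movie ONi as linear as the white-noise ONi
  expect_lt(abs(output_nonlinearity_index(res$outfn_movie)), 0.2)
})
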