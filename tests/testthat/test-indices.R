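test_that("hyperpolarization index boundary and formula values", {
  expect_equal(hyperpolarization_index(5, -5), 0)
  expect_equal(hyperpolarization_index(5, 0), 1)
  expect_equal(hyperpolarization_index(2, -6), -0.5)
  expect_true(is.na(hyperpolarization_index(0, 0)))
  # trace interface: extrema are taken internally
  t <- seq(0, 1, by = 1e-3)
  expect_equal(hyperpolarization_index(5 * sin(pi * t), -5 * sin(pi * t)), 0)
})

test_that("output nonlinearity index canonical shapes", {
  g <- seq(-2, 2, length.out = 40)
  mk <- function(v) structure(data.frame(generator = g, voltage = v,
                                         count = rep(100, 40)),
                              class = c("output_function", "data.frame"))
  expect_equal(output_nonlinearity_index(mk(g)), 0)
  expect_equal(output_nonlinearity_index(mk(pmax(g, 0))), 1)
  # saturating shape: S_pos = 1, S_neg = 3 -> -0.5
  v <- ifelse(g < 0, 3 * g, g)
  expect_equal(output_nonlinearity_index(mk(v)), -0.5)
  one_sided <- mk(g)[g > 0, ]
  expect_true(is.na(output_nonlinearity_index(one_sided)))
})

test_that("SNi: analytic Fourier values and rescaling invariance", {
  rate <- 1000
  t <- (1:rate) / rate
  pat <- 2 * sin(2 * pi * 2 * t)
  unif <- 2 * sin(2 * pi * 1 * t)
  sni <- spatial_nonlinearity_index(list(halves = pat), unif, rate)
  expect_equal(unname(sni$sni["halves"]), 1, tolerance = 1e-12)
  expect_equal(sni$sni_max, 1, tolerance = 1e-12)
  # zero pattern response
  expect_equal(unname(spatial_nonlinearity_index(list(halves = pat * 0),
                                                 unif, rate)$sni_max), 0)
  # invariant to common rescaling of both traces
  sni2 <- spatial_nonlinearity_index(list(halves = 5 * pat), 5 * unif, rate)
  expect_equal(sni2$sni_max, sni$sni_max, tolerance = 1e-12)
  # 4 Hz power counts toward the index
  pat24 <- sin(2 * pi * 2 * t) + sin(2 * pi * 4 * t)
  sni3 <- spatial_nonlinearity_index(list(halves = pat24),
                                     sin(2 * pi * t), rate)
  expect_equal(sni3$sni_max, 2, tolerance = 1e-12)
  # dead cell: normalization below the noise floor is flagged
  expect_true(spatial_nonlinearity_index(list(halves = pat), unif * 0,
                                         rate)$flagged)
})

test_that("cycle-average FFT power equals direct sinusoid regression", {
  rate <- 500
  t <- (1:rate) / rate
  set.seed(1)
  x <- 1.3 * sin(2 * pi * t + 0.4) + 0.6 * cos(2 * pi * 2 * t) +
    0.2 * sin(2 * pi * 4 * t - 1)
  x <- x - mean(x)
  for (f in c(1, 2, 4)) {
    p_fft <- bipolarLN:::cycle_power(x, rate, f)
    fit <- stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
    amp2 <- sum(stats::coef(fit)[2:3]^2)
    p_reg <- amp2 * (length(x) / 2)^2
    expect_lt(abs(p_fft - p_reg) / max(p_fft, 1), 1e-9)
  }
})

test_that("grating SNi boundary values", {
  rate <- 1000
  t <- (1:rate) / rate
  f1 <- lapply(1:8, function(k) sin(2 * pi * t + k))
  expect_equal(grating_nonlinearity_index(list(p80 = f1),
                                          rate)$sni_grating, 0,
               tolerance = 1e-12)
  # all phases respond at 2 Hz with the power of the best 1 Hz phase -> 1
  base <- sin(2 * pi * t)
  mix <- lapply(1:8, function(k) sin(2 * pi * 2 * t + k) + base)
  got <- grating_nonlinearity_index(list(p80 = mix), rate)$sni_grating
  expect_equal(got, 1, tolerance = 1e-9)
})

test_that("sustained-transient index: analytic decay value", {
  rate <- 1000
  t <- (1:500) / rate
  # square step holding its peak
  expect_equal(sustained_transient_index(rep(4, 500), rate), 1)
  # decayed to baseline before offset
  expect_equal(sustained_transient_index(c(rep(4, 10), rep(0, 490)), rate), 0)
  # exponential decay tau = 100 ms from peak at onset:
  # STi = mean(exp(-t/tau)) over [450, 500] ms = 2(e^-4.5 - e^-5) ~ 0.00874
  resp <- exp(-(0:499) / 100)
  got <- sustained_transient_index(resp, rate)
  expect_equal(got, 0.0087, tolerance = 0.01)
  expect_true(is.na(sustained_transient_index(rep(0, 500), rate)))
})

test_that("latency: constructed crossing and peak times", {
  rate <- 1000
  resp <- c(rep(0, 40), seq(0, 10, length.out = 100), rep(10, 360))
  lat <- response_latency(resp, baseline_sd = 1, rate_hz = rate)
  # ramp crosses 3 sd = 3 at sample 41 + 30
  expect_equal(lat$onset_ms, 70, tolerance = 2)
  expect_equal(lat$time_to_peak_ms, 139)
  # instant step: onset at the first sample
  expect_equal(response_latency(rep(5, 500), 1, rate)$onset_ms, 0)
  expect_true(is.na(response_latency(rep(0.1, 500), 1, rate)$onset_ms))
})

test_that("difference-of-Gaussians spot profile fit", {
  dog <- function(d, kc, sc, ks, ss) {
    r <- d / 2
    kc * (1 - exp(-r^2 / (2 * sc^2))) - ks * (1 - exp(-r^2 / (2 * ss^2)))
  }
  d <- c(10, 25, 50, 75, 100, 150, 200, 300, 400, 500, 800, 1200)
  v <- dog(d, 8, 35, 3, 120)
  fit <- fit_dog_profile(d, v)
  expect_true(fit$converged)
  expect_equal(fit$k_center, 8, tolerance = 0.02)
  expect_equal(fit$sigma_center_um, 35, tolerance = 0.02)
  expect_equal(fit$k_surr, 3, tolerance = 0.02)
  expect_equal(fit$sigma_surround_um, 120, tolerance = 0.02)
  expect_equal(fit$local_spot_diameter_um, 100)  # closest to 3 sigma = 105
  # no surround: center-surround index ~ 0
  v0 <- dog(d, 8, 35, 0, 120)
  expect_equal(fit_dog_profile(d, v0)$center_surround_index, 0,
               tolerance = 0.02)
  # formula evaluation: V_all = 10, V_large = 6 -> 0.4
  vv <- c(1, 2, 4, 7, 9, 10, 9.5, 8.5, 7.5, 6, 5, 4.5)
  expect_equal(fit_dog_profile(d, vv)$center_surround_index, 0.4)
})

test_that("amplitude modulation across temporal frequencies", {
  t <- seq(0, 2, by = 1e-3)
  resp <- list(f025 = rep(1, 100), f1 = 3 * sin(2 * pi * t))
  am <- frequency_sweep_amplitude(resp)
  expect_equal(unname(am["f025"]), 0)
  expect_equal(unname(am["f1"]), 6, tolerance = 1e-3)
})

test_that("oscillation frequency from the step-response window", {
  rate <- 1000
  t <- (1:1100) / rate
  resp <- sin(2 * pi * 30 * t)
  out <- oscillation_frequency(resp, rate)
  expect_equal(out$frequency_hz, 30)
  expect_true(out$confident)
  # stronger 10 Hz component wins over 25 Hz
  two <- 2 * sin(2 * pi * 10 * t) + sin(2 * pi * 25 * t)
  expect_equal(oscillation_frequency(two, rate)$frequency_hz, 10)
  # white noise: low confidence
  set.seed(2)
  wn <- oscillation_frequency(rnorm(1100), rate)
  expect_false(wn$confident)
})

test_that("grating spatial scale: logistic midpoint recovery", {
  x <- c(10, 15, 20, 25, 30, 40, 60, 90, 120)
  y <- 2 + 28 / (1 + exp(-(x - 20) / 4))
  fit <- grating_spatial_scale(x, y)
  expect_false(fit$flagged)
  expect_equal(fit$scale_um, 20, tolerance = 0.05)
  # step-like data: midpoint bracketed by the jump
  ys <- ifelse(x <= 20, 1, 30)
  fs <- grating_spatial_scale(x, ys)
  expect_gt(fs$scale_um, 20)
  expect_lt(fs$scale_um, 40)
  # flat curve flagged
  expect_true(grating_spatial_scale(x, rep(5, length(x)))$flagged)
})

test_that("indices stay bounded for arbitrary finite inputs", {
  set.seed(9)
  for (i in 1:25) {
    vd <- stats::rnorm(1, 0, 5); vh <- stats::rnorm(1, 0, 5)
    h <- hyperpolarization_index(vd, vh)
    if (!is.na(h)) expect_true(h >= -1 && h <= 1)
    g <- seq(-2, 2, length.out = 20)
    ofn <- data.frame(generator = g, voltage = stats::rnorm(20))
    o <- output_nonlinearity_index(ofn)
    if (!is.na(o)) expect_true(o >= -1 && o <= 1)
  }
})

test_that("split-spot responses of a rectified cell persist across reversal frequencies", {
  cell <- rectified_cell(0)
  cv <- default_canvas()
  amp <- vapply(c(0.25, 0.5, 1, 2), function(f) {
    st <- reversing_spot("halves", canvas = cv, duration_s = 2 / f,
                         reversal_hz = f)
    tr <- simulate_voltage(cell, st)
    max(tr$samples_mv[1001:length(tr)]) -
      min(tr$samples_mv[1001:length(tr)])
  }, numeric(1))
  # amplitude modulation roughly stable over 0.25-2 Hz
  expect_lt(max(amp) / min(amp), 2)
})
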