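test_that("flashed uniform spot renders the right frames", {
  cv <- stim_canvas(200, pixel_size_um = 2.5)
  st <- render_spot(spot_spec(diameter_um = 100, contrast = -1,
                              mode = "flash", stim_duration_s = 0.5,
                              background_duration_s = 0),
                    cv, frame_rate_hz = 60)
  expect_equal(dim(st$frames)[1], 30)
  f1 <- st$frames[1, , ]
  expect_setequal(unique(as.vector(f1)), c(0, -1))
  # disk area matches pi r^2 to within the pixelated boundary
  expect_equal(sum(f1 == -1) * 2.5^2, pi * 50^2, tolerance = 0.02)
  # all frames identical during the flash
  expect_equal(st$frames[30, , ], f1)
  # pixels outside the disk are background on every frame
  expect_true(all(st$frames[, 1, 1] == 0))
})

test_that("patterned spots are contrast balanced and reversing flips sign", {
  cv <- stim_canvas(200, pixel_size_um = 2.5)
  for (pat in c("halves", "quarters", "check25", "check10")) {
    st <- reversing_spot(pat, canvas = cv, duration_s = 2)
    f <- st$frames[61, , ]  # first stimulus frame (after 1 s lead)
    px_per_square <- (25 / 2.5)^2
    expect_lte(abs(sum(f)), px_per_square,
               label = sprintf("pattern %s balance", pat))
    expect_setequal(sort(unique(as.vector(f))), c(-1, 0, 1))
    # reversal half a period later: frames(t + T/2) = -frames(t)
    expect_equal(st$frames[61 + 30, , ], -f)
  }
})

test_that("check25 pattern alternates sign at 25 um", {
  cv <- stim_canvas(200, pixel_size_um = 2.5)
  st <- reversing_spot("check25", canvas = cv, duration_s = 2)
  f <- st$frames[61, , ]
  mid <- 40  # row through the spot center
  row <- f[mid, ]
  inside <- which(row != 0)
  lag <- 10  # 25 um at 2.5 um/px
  # pixel-count oracle: products across a 25 um shift are negative inside
  pairs <- inside[(inside + lag) %in% inside]
  expect_true(all(row[pairs] * row[pairs + lag] == -1))
})

test_that("spot exceeding the canvas reports the overhang", {
  cv <- stim_canvas(100, pixel_size_um = 2.5)
  expect_error(render_spot(spot_spec(diameter_um = 150), cv), "25.0 um")
})

test_that("checkerboard noise is deterministic, binary and balanced", {
  spec <- noise_spec(duration_s = 40, extent_um = 120, seed = 7)
  a <- render_checkerboard_noise(spec)
  b <- render_checkerboard_noise(spec)
  expect_identical(a$frames, b$frames)
  expect_setequal(unique(as.vector(a$frames)), c(-1, 1))
  # binomial oracle: fraction of +1 within 4 sigma of 1/2
  n <- length(a$frames)
  frac <- mean(a$frames == 1)
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / n))
  # per-square means shrink toward 0
  sq_means <- apply(a$frames, c(2, 3), mean)
  expect_lt(max(abs(sq_means)), 5 / sqrt(dim(a$frames)[1]))
  expect_error(render_checkerboard_noise(
    noise_spec(duration_s = 1, extent_um = 100, square_size_um = 30)),
    "multiple")
})

test_that("frozen segments repeat verbatim and leave the fresh stream intact", {
  spec <- noise_spec(duration_s = 100, extent_um = 120, seed = 3,
                     frozen_length_frames = 300,
                     frozen_period_frames = 1200)
  st <- render_checkerboard_noise(spec)
  sched <- bipolarLN:::frozen_schedule(dim(st$frames)[1], 300, 1200)
  ins <- which(sched$within == 1)
  expect_gte(length(ins), 2)
  expect_identical(st$frames[ins[1] + 0:299, , ],
                   st$frames[ins[2] + 0:299, , ])
  # fresh frames equal the corresponding frames of an uninterrupted render
  plain <- render_checkerboard_noise(noise_spec(duration_s = 100,
                                                extent_um = 120, seed = 3))
  fresh <- which(!sched$frozen)
  expect_identical(st$frames[fresh[1:1200], , ], plain$frames[1:1200, , ])
})

test_that("full-field Gaussian noise has the configured sd and frozen blocks", {
  spec <- noise_spec(layout = "fullfield", distribution = "gaussian",
                     sd = 0.3, duration_s = 4000, update_rate_hz = 25,
                     seed = 5)
  st <- render_fullfield_noise(spec)
  v <- as.vector(st$frames)
  expect_equal(stats::sd(v), 0.3, tolerance = 0.01)
  expect_lt(abs(mean(v)), 0.01)
  spec0 <- noise_spec(layout = "fullfield", distribution = "gaussian",
                      sd = 0, duration_s = 2, seed = 5)
  expect_true(all(render_fullfield_noise(spec0)$frames == 0))
  specf <- noise_spec(layout = "fullfield", distribution = "gaussian",
                      duration_s = 120, update_rate_hz = 30, seed = 6,
                      frozen_length_frames = 300,
                      frozen_period_frames = 900)
  stf <- render_fullfield_noise(specf)
  sched <- bipolarLN:::frozen_schedule(dim(stf$frames)[1], 300, 900)
  ins <- which(sched$within == 1)
  expect_identical(stf$frames[ins[1] + 0:299, 1, 1],
                   stf$frames[ins[2] + 0:299, 1, 1])
})

test_that("sine gratings: phases, zero spatial mean, reversal", {
  cv <- stim_canvas(320, pixel_size_um = 2.5)
  gr <- render_grating(grating_spec(spatial_period_um = 80, n_phases = 8,
                                    duration_s = 2), cv, frame_rate_hz = 60)
  expect_length(gr, 8)
  # phase offsets are 10 um apart: phase k equals phase 0 shifted 4 px
  r0 <- gr[[1]]$frames[1, 1, ]
  r1 <- gr[[2]]$frames[1, 1, ]
  expect_equal(r1[5:128], r0[1:124], tolerance = 1e-12)
  # spatial mean over one full period vanishes (analytic sine integral)
  expect_lt(abs(mean(r0[1:32])), 1e-12)
  # contrast reversal at 1 Hz
  expect_equal(gr[[1]]$frames[31, , ], -gr[[1]]$frames[1, , ])
  # zero amplitude -> background
  g0 <- render_grating(grating_spec(amplitude = 0, duration_s = 0.5), cv)
  expect_true(all(g0[[1]]$frames == 0))
  expect_error(render_grating(grating_spec(spatial_period_um = 4), cv),
               "period")
})

test_that("movie surrogate matches target statistics and 1/f spectrum", {
  mv <- render_movie_surrogate(duration_s = 20, seed = 9)
  expect_lt(abs(mean(mv$frames)), 0.01)
  expect_equal(stats::sd(as.vector(mv$frames)), 0.45, tolerance = 0.02)
  expect_identical(render_movie_surrogate(duration_s = 2, seed = 4)$frames,
                   render_movie_surrogate(duration_s = 2, seed = 4)$frames)
  # spatial amplitude spectrum decays with frequency (periodogram oracle)
  f <- mv$frames[1, , ]
  a <- Mod(stats::fft(f))
  n <- nrow(f)
  freqs <- 1:(n %/% 2 - 1)
  slope <- stats::coef(stats::lm(log(a[freqs + 1, 1]) ~ log(freqs)))[2]
  expect_lt(slope, 0)
})

test_that("renderers are pure functions of spec and seed", {
  cv <- stim_canvas(150)
  s1 <- render_spot(spot_spec(diameter_um = 80), cv)
  s2 <- render_spot(spot_spec(diameter_um = 80), cv)
  expect_identical(s1$frames, s2$frames)
})
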