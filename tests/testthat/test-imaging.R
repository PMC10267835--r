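test_that("background model is reproducible and well formed", {
  bg1 <- synth_background(c(64, 64), seed = 3)
  bg2 <- synth_background(c(64, 64), seed = 3)
  expect_identical(bg1$M, bg2$M)
  expect_identical(bg1$S, bg2$S)
  expect_true(all(bg1$S >= 0))
  frac <- mean(bg1$mask)
  expect_gt(frac, 0.3); expect_lt(frac, 0.8)
  # per-pixel sample mean over many frames concentrates on M
  set.seed(1)
  bg <- synth_background(c(16, 16), seed = 5)
  acc <- matrix(0, 16, 16)
  n <- 3000
  for (i in seq_len(n)) acc <- acc + draw_background(bg)
  expect_true(all(abs(acc / n - bg$M) <= 4 * bg$S / sqrt(n)))
})

test_that("Brownian tracks respect diffusion and confinement", {
  cfg <- imaging_config(frame_interval = 1, n_frames = 50, diffusion = 0.4,
                        frame_dim = c(256, 256))
  bg <- synth_background(c(256, 256), seed = 2)
  # D = 0: the spot never moves
  tr0 <- brownian_track(cfg, bg$mask, D = 0, seed = 1)
  expect_equal(var(tr0$row) + var(tr0$col), 0)
  # tracks stay inside the mask (with the edge margin)
  trs <- lapply(1:300, function(i) brownian_track(cfg, bg$mask, seed = i))
  inside <- vapply(trs, function(tr)
    all(bg$mask[cbind(round(tr$row), round(tr$col))]), logical(1))
  expect_true(all(inside))
  # ensemble MSD(dt) ~ 4 D dt for small lags
  for (dt in c(1, 3)) {
    d2 <- vapply(trs, function(tr) {
      dr <- tr$row[-(1:dt)] - tr$row[seq_len(nrow(tr) - dt)]
      dc <- tr$col[-(1:dt)] - tr$col[seq_len(nrow(tr) - dt)]
      mean(dr^2 + dc^2)
    }, numeric(1))
    expect_equal(mean(d2), 4 * 0.4 * dt, tolerance = 0.08)
  }
  # unconfined steps pass a normality check
  steps <- unlist(lapply(trs[1:50], function(tr) diff(tr$row)))
  expect_gt(stats::shapiro.test(sample(steps, 1000))$p.value, 0.01)
})

test_that("rendering is linear in spot amplitude", {
  cfg <- imaging_config(frame_interval = 1, n_frames = 6,
                        frame_dim = c(64, 64), snr = 5)
  bg <- synth_background(c(64, 64), seed = 8)
  bg$S[] <- 0                      # noiseless background isolates the PSF
  amps <- c(0, 1, 2, 4, 8, 16)
  track <- data.frame(frame = 0:5, row = rep(32.3, 6), col = rep(30.6, 6))
  vid <- render_video(bg, matrix(amps, 1), list(track), cfg, gain = 3)
  tr <- extract_intensity(vid, track)
  fit <- lm(tr$values ~ amps)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_gt(coef(fit)[2], 0)
  # doubling amplitudes doubles the extracted readout (zero intercept here)
  expect_equal(tr$values[amps == 2] - tr$values[amps == 0],
               2 * (tr$values[amps == 1] - tr$values[amps == 0]),
               tolerance = 1e-8)
})

test_that("zero-intensity spots reduce to pure background readout", {
  cfg <- imaging_config(frame_interval = 1, n_frames = 40,
                        frame_dim = c(64, 64))
  bg <- synth_background(c(64, 64), seed = 4)
  # the gain multiplies only the spot amplitude, so dark spots are
  # bit-identical at any gain: the video is background alone
  z1 <- simulate_nct_traces(matrix(0, 6, 40), bg, cfg, gain = 50, seed = 2)
  z2 <- simulate_nct_traces(matrix(0, 6, 40), bg, cfg, gain = 0.1, seed = 2)
  expect_identical(unclass(z1)[, ], unclass(z2)[, ])
  # readout fluctuates (pixel noise + motion over background structure)
  # but stays small against a calibrated signal at SNR ~ 6
  gain <- calibrate_gain(bg, imaging_config(frame_interval = 1,
                                            n_frames = 40, snr = 6.2),
                         19.33, seed = 1)
  sig <- gain * nctmux:::psf_disk_response(cfg$psf_sigma) * 19.33
  expect_lt(abs(mean(z1)), 0.35 * sig)
  expect_gt(sd(as.vector(z1)), 0)
})

test_that("SNR calibration hits its definition", {
  cfg <- imaging_config(frame_interval = 5, n_frames = 64, snr = 6.2)
  bg <- synth_background(c(512, 512), seed = 31)
  gain <- calibrate_gain(bg, cfg, 19.33, seed = 1)
  x <- simulate_nct_traces(matrix(19.33, 15, 64), bg, cfg, gain, seed = 5)
  z <- simulate_nct_traces(matrix(0, 30, 64), bg, cfg, gain, seed = 6)
  achieved <- mean(x) / sd(as.vector(z))
  expect_equal(achieved, 6.2, tolerance = 0.2)
})

test_that("patch shortcut matches full-frame render-then-extract", {
  cfg <- imaging_config(frame_interval = 1, n_frames = 30,
                        frame_dim = c(96, 96))
  bg <- synth_background(c(96, 96), seed = 12)
  track <- brownian_track(cfg, bg$mask, seed = 3)
  ump <- matrix(10, 1, 30)
  vid <- render_video(bg, ump, list(track), cfg, gain = 4)
  full <- extract_intensity(vid, track)$values
  patch <- as.vector(simulate_nct_traces(ump, bg, cfg, gain = 4, seed = 9,
                                         tracks = list(track)))
  # same mean response and comparable spread (independent noise draws)
  expect_equal(mean(patch), mean(full), tolerance = 4 * sd(full) / sqrt(30))
  expect_lt(abs(sd(patch) / sd(full) - 1), 0.8)
})

test_that("photobleaching decays signal exponentially", {
  tr <- structure(list(times = c(0, 10, 20), values = c(8, 8, 8),
                       spot_id = "s", construct = "c"),
                  class = "intensity_trace")
  expect_equal(apply_photobleach(tr, 0)$values, c(8, 8, 8))
  rate <- log(2) / 10
  expect_equal(apply_photobleach(tr, rate)$values, c(8, 4, 2))
  m <- matrix(1, 2, 3); attr(m, "times") <- c(0, 10, 20)
  expect_equal(unname(apply_photobleach(m, rate)[1, ]), c(1, 0.5, 0.25))
})

test_that("video TIFF round-trip preserves frames to 16-bit precision", {
  cfg <- imaging_config(frame_interval = 1, n_frames = 3,
                        frame_dim = c(32, 32))
  bg <- synth_background(c(32, 32), seed = 2)
  set.seed(1)
  vid <- render_video(bg, matrix(5, 1, 3),
                      list(data.frame(frame = 0:2, row = rep(16, 3),
                                      col = rep(16, 3))), cfg, gain = 2)
  path <- withr::local_tempfile(fileext = ".tif")
  p <- write_video_tiff(vid, path)
  sc <- attr(p, "scale")
  back <- read_video_tiff(path, scale = sc)
  expect_equal(dim(back), dim(vid$frames))
  expect_equal(back, vid$frames, tolerance = diff(sc) / 2^15)
})

test_that("render_video validates trace/track agreement", {
  cfg <- imaging_config(frame_interval = 1, n_frames = 4,
                        frame_dim = c(32, 32))
  bg <- synth_background(c(32, 32), seed = 1)
  expect_error(render_video(bg, matrix(1, 2, 4), list(), cfg, gain = 1),
               "one track per trace")
})
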