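test_that("marker segmentation reuses the spot detector", {
  ts <- simulate_telomere_scene(n_telomeres = 40, n_with_sensor = 10,
                                image_shape = c(z = 10L, y = 160L, x = 160L),
                                noise = noise_off(), seed = 9)
  obj <- segment_marker_foci(ts$marker, nucleus = ts$nucleus_roi)
  expect_identical(nrow(obj), 40L)
  expect_true(all(obj$n_voxels >= 2 & obj$n_voxels <= 50))

  blank <- image_stack(array(0, dim = c(4, 32, 32)), axes = c("z", "y", "x"))
  expect_identical(nrow(segment_marker_foci(blank)), 0L)

  # one oversized blob is rejected by the maximum size filter
  arr <- array(50, dim = c(10, 64, 64))
  blob <- rloopquant:::.add_focus(array(50, dim = c(10, 64, 64)),
                                  c(31, 31, 4.5),
                                  c(z = 2.4, y = 2.6, x = 2.6), 800)
  big <- image_stack(round(blob), axes = c("z", "y", "x"))
  expect_identical(nrow(segment_marker_foci(big)), 0L)
})

test_that("the above-background fraction follows its construction", {
  ts <- simulate_telomere_scene(n_telomeres = 100, n_with_sensor = 32,
                                sensor_contrast = 10,
                                noise = noise_off(), seed = 3)
  obj <- segment_marker_foci(ts$marker, nucleus = ts$nucleus_roi)
  res <- fraction_above_background(obj, ts$sensor, ts$background_roi)
  expect_identical(res$n_total, 100L)
  expect_identical(res$fraction, 0.32)

  # uniform sensor: nothing is above background at k_sd = 2
  unif <- image_stack(array(60, dim = dim(ts$sensor$data)),
                      axes = c("z", "y", "x"))
  r0 <- fraction_above_background(obj, unif, ts$background_roi)
  expect_identical(r0$fraction, 0)

  # infinite margin: fraction 0 by the limit
  rinf <- fraction_above_background(obj, ts$sensor, ts$background_roi,
                                    k_sd = Inf)
  expect_identical(rinf$fraction, 0)

  # no objects: undefined fraction reported as NA
  rempty <- fraction_above_background(obj[0, ], ts$sensor, ts$background_roi)
  expect_true(is.na(rempty$fraction))
})

test_that("the fraction is monotone in k_sd and small under the null", {
  ts <- simulate_telomere_scene(n_telomeres = 60, n_with_sensor = 0,
                                image_shape = c(z = 10L, y = 160L, x = 160L),
                                seed = 21)
  obj <- segment_marker_foci(ts$marker, nucleus = ts$nucleus_roi)
  fr <- vapply(c(0, 1, 2, 3), function(k)
    fraction_above_background(obj, ts$sensor, ts$background_roi,
                              k_sd = k)$fraction, 0)
  expect_true(all(diff(fr) <= 0))
  # under the null the 2-sd criterion flags at most a small tail
  expect_lte(fr[3], 0.023 + 3 * sqrt(0.023 * 0.977 / nrow(obj)))
})

test_that("line profiles interpolate bilinearly", {
  m <- matrix(5, 20, 20)
  st <- image_stack(m, axes = c("y", "x"))
  pr <- line_profile(st, c(2, 3), c(15, 3))
  expect_true(all(pr$ch1 == 5))

  ramp <- matrix(rep(0:19, each = 20), 20, 20)  # I(x, y) = x
  st2 <- image_stack(ramp, axes = c("y", "x"))
  pr2 <- line_profile(st2, c(1, 10), c(17, 10))
  expect_equal(pr2$ch1, pr2$x, tolerance = 1e-12)

  # profile across a Gaussian spot peaks at the projected center
  g <- outer(exp(-((0:29) - 14)^2 / 8), exp(-((0:29) - 17)^2 / 8))
  st3 <- image_stack(g * 100, axes = c("y", "x"))
  pr3 <- line_profile(st3, c(5, 14), c(28, 14))
  expect_lt(abs(pr3$x[which.max(pr3$ch1)] - 17), 1.01)

  expect_error(line_profile(st, c(3, 3), c(3, 3)), "zero-length")
})

test_that("locus tracking is exact on static symmetric spots", {
  sim <- simulate_locus_timelapse(n_frames = 12, dt_s = 8,
                                  noise = noise_off(), seed = 1)
  tr <- track_locus(sim$stack, 1, 2,
                    init_xy = sim$truth$center[c("x", "y")] + c(2, -1))
  expect_lt(max(abs(tr$x - sim$truth$center["x"])), 0.05)
  expect_lt(max(abs(tr$y - sim$truth$center["y"])), 0.05)
  expect_lt(max(abs(tr$z - sim$truth$center["z"])), 0.05)
  expect_false(any(tr$lost))
})

test_that("tracking follows a slowly drifting marker", {
  # hand-rendered drifting spot: 0.2 px/frame in x
  nz <- 7; ny <- 40; nx <- 40; nt <- 20
  arr <- array(0, dim = c(nt, 2, nz, ny, nx))
  xs <- 15 + 0.2 * (0:(nt - 1))
  for (i in 1:nt) {
    ph <- rloopquant:::.add_focus(array(20, dim = c(nz, ny, nx)),
                                  c(xs[i], 20, 3),
                                  c(z = 0.9, y = 0.7, x = 0.7), 300)
    arr[i, 1, , , ] <- round(ph)
    arr[i, 2, , , ] <- 20
  }
  st <- image_stack(arr, axes = c("t", "c", "z", "y", "x"),
                    time_interval_s = 8)
  tr <- track_locus(st, 1, 2, init_xy = c(15, 20))
  expect_lt(max(abs(tr$x - xs)), 0.5)
  expect_lt(max(abs(tr$y - 20)), 0.5)

  # sensor channel at pure background reads ~0
  expect_lt(max(abs(tr$sensor)), 1)
})

test_that("fluctuation cycles recover the burst period", {
  sim <- simulate_locus_timelapse(burst_period_s = 45, burst_duration_s = 20,
                                  n_frames = 75, dt_s = 8, seed = 3)
  tr <- track_locus(sim$stack, 1, 2,
                    init_xy = sim$truth$center[c("x", "y")])
  cyc <- detect_fluctuation_cycles(tr, smooth_window = 3, min_prominence = 0.5)
  expect_gte(cyc$n_peaks, 2)
  expect_true(cyc$median_period_s >= 37 && cyc$median_period_s <= 53)

  # noise-free series recovers the burst count exactly (series long enough
  # that the final burst completes inside the recording)
  sim0 <- simulate_locus_timelapse(burst_period_s = 45, burst_duration_s = 20,
                                   n_frames = 78, dt_s = 8,
                                   noise = noise_off(), seed = 4)
  tr0 <- track_locus(sim0$stack, 1, 2,
                     init_xy = sim0$truth$center[c("x", "y")])
  cyc0 <- detect_fluctuation_cycles(tr0, smooth_window = 1,
                                    min_prominence = 0.5)
  expect_identical(cyc0$n_peaks, nrow(sim0$truth$bursts))

  flat <- data.frame(time_s = seq(0, 80, by = 8), sensor = rep(3, 11))
  c0 <- detect_fluctuation_cycles(flat)
  expect_identical(c0$n_peaks, 0L)
  expect_true(is.na(c0$median_period_s))

  single <- data.frame(time_s = 0:10,
                       sensor = c(0, 0, 0, 1, 4, 6, 4, 1, 0, 0, 0))
  c1 <- detect_fluctuation_cycles(single, smooth_window = 1)
  expect_identical(c1$n_peaks, 1L)
  expect_true(is.na(c1$median_period_s))
})

test_that("treatment response tests flag the transcription block", {
  set.seed(5)
  ncell <- 35
  pre <- rnorm(ncell, 100, 15)
  # signal decays to background (tau chosen so it is gone by ~30 min),
  # 10-min frames; washout restores the pre-treatment distribution
  t_post <- seq(10, 60, by = 10) * 60
  post <- vapply(t_post, function(t) {
    rnorm(ncell, 100 * exp(-t / 360), 8)
  }, numeric(ncell))
  res <- treatment_response_test(pre, post)
  expect_true(all(res$p[2:6] < 0.05))

  wash <- matrix(rnorm(ncell * 2, 100, 15), ncell)
  res_w <- treatment_response_test(pre, wash)
  expect_true(all(res_w$p > 0.05))

  same <- treatment_response_test(pre, cbind(pre, pre))
  expect_true(all(same$p == 1))

  expect_error(treatment_response_test(1, matrix(1:2, 1)), "2 cells")
})
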