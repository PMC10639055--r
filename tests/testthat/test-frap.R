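test_that("frame registration recovers integer translations", {
  set.seed(3)
  base <- matrix(50, 40, 40)
  base[15:25, 15:25] <- 400
  base <- base + matrix(rnorm(1600, 0, 5), 40, 40)

  # identical frames -> zero shifts
  arr <- array(0, dim = c(3, 40, 40))
  for (i in 1:3) arr[i, , ] <- base
  reg <- register_frames(image_stack(arr, axes = c("t", "y", "x"),
                                     time_interval_s = 1))
  expect_true(all(reg$shifts == 0))

  # a frame translated by (3, -2) is brought back
  sx <- 3; sy <- -2
  shifted <- matrix(50, 40, 40)
  ys <- max(1, 1 + sy):min(40, 40 + sy)
  xs <- max(1, 1 + sx):min(40, 40 + sx)
  shifted[ys, xs] <- base[ys - sy, xs - sx]
  arr[3, , ] <- shifted
  reg <- register_frames(image_stack(arr, axes = c("t", "y", "x"),
                                     time_interval_s = 1))
  expect_equal(c(reg$shifts$dx[3], reg$shifts$dy[3]), c(-sx, -sy))

  # constant frames: zero shift with a warning
  arr[2, , ] <- 7
  expect_warning(register_frames(image_stack(arr, axes = c("t", "y", "x"),
                                             time_interval_s = 1)),
                 "constant")
})

test_that("the FRAP measurement triple is read off the movie", {
  # uniform frames: all three series are the frame value
  arr <- array(0, dim = c(4, 60, 60))
  for (i in 1:4) arr[i, , ] <- i * 10
  st <- image_stack(arr, axes = c("t", "y", "x"), time_interval_s = 0.3)
  bleach <- circle_roi(c(20, 30), 11)
  cell <- polygon_roi(rbind(c(5, 5), c(45, 5), c(45, 55), c(5, 55)))
  bg <- polygon_roi(rbind(c(50, 5), c(58, 5), c(58, 15), c(50, 15)))
  fe <- measure_frap_signals(st, bleach, cell, bg, n_pre = 2)
  expect_equal(fe$roi_series, c(10, 20, 30, 40))
  expect_equal(fe$background_series, c(10, 20, 30, 40))
  expect_equal(fe$reference_series, c(10, 20, 30, 40))

  # overlapping cell/background ROIs are rejected
  bad_bg <- polygon_roi(rbind(c(40, 5), c(58, 5), c(58, 15), c(40, 15)))
  expect_error(measure_frap_signals(st, bleach, cell, bad_bg, 2), "overlap")

  # rendered movie with acquisition bleaching, no noise: the reference
  # series is proportional to (1 - beta)^frame exactly
  cfg <- frap_sim_config(fractions = cbind(f = 1, k = 0.2), n_post = 30,
                         acquisition_bleach_rate = 0.004,
                         background_photons = 0, noise = noise_off(), seed = 1)
  mv <- simulate_frap_movie(cfg)
  fe2 <- measure_frap_signals(mv$stack, mv$bleach_roi, mv$cell_roi,
                              mv$background_roi, n_pre = 5)
  frames <- seq_along(fe2$reference_series) - 1
  ratio <- fe2$reference_series / (0.996^frames)
  expect_lt(diff(range(ratio)) / mean(ratio), 0.005)  # quantization only
  expect_true(all(fe2$background_series == 0))
})

test_that("double normalization anchors are exact and invert the generator", {
  for (seed in 1:5) {
    cfg <- frap_sim_config(fractions = cbind(f = 0.8, k = 0.5),
                           immobile_fraction = 0.1,
                           acquisition_bleach_rate = 0.002, seed = seed)
    nc <- normalize_frap(simulate_frap_experiment(cfg)$experiment)
    expect_equal(mean(nc$values[1:5]), 1.0, tolerance = 1e-12)
    expect_identical(nc$values[6], 0)
  }

  # noise-free with bleaching: normalized curve equals ground truth <= 1e-6
  cfg <- frap_sim_config(fractions = cbind(f = c(0.5, 0.4), k = c(1, 0.05)),
                         immobile_fraction = 0.1, bleach_depth = 0.85,
                         acquisition_bleach_rate = 0.005,
                         noise = noise_off(), seed = 2)
  sim <- simulate_frap_experiment(cfg)
  nc <- normalize_frap(sim$experiment)
  expect_lt(max(abs(nc$values[6:125] - sim$truth$recovery)), 1e-6)

  # error paths: non-positive reference, degenerate bleach
  fe <- frap_experiment(0:9, rep(5, 10), rep(5, 10), rep(5, 10), n_pre = 3)
  expect_error(normalize_frap(fe), "reference")
  fe2 <- frap_experiment(0:9, rep(5, 10), rep(1, 10), rep(9, 10), n_pre = 3)
  expect_error(normalize_frap(fe2), "degenerate")
})

test_that("time-to-fraction reads the analytic crossing times", {
  k <- log(2) / 25
  cfg <- frap_sim_config(fractions = cbind(f = 1, k = k), n_post = 600,
                         dt_s = 0.3, acquisition_bleach_rate = 0,
                         noise = noise_off(), seed = 1)
  nc <- normalize_frap(simulate_frap_experiment(cfg)$experiment)
  expect_equal(time_to_fraction(nc, 0.5), 25, tolerance = 0.15)
  expect_equal(time_to_fraction(nc, 0.8), log(5) / k, tolerance = 0.15)

  # plateau at 0.65 never reaches 80%
  cfg2 <- frap_sim_config(fractions = cbind(f = 0.65, k = 0.3),
                          immobile_fraction = 0.35, noise = noise_off(),
                          seed = 1)
  nc2 <- normalize_frap(simulate_frap_experiment(cfg2)$experiment)
  expect_true(is.na(time_to_fraction(nc2, 0.8)))
  expect_error(time_to_fraction(nc2, 1.2), "fraction")
})

test_that("plateau is the terminal-window mean", {
  cfg <- frap_sim_config(fractions = cbind(f = 0.65, k = 2),
                         immobile_fraction = 0.35, n_post = 100,
                         noise = noise_off(), seed = 1)
  nc <- normalize_frap(simulate_frap_experiment(cfg)$experiment)
  expect_equal(plateau(nc), 0.65, tolerance = 1e-6)

  cfg2 <- frap_sim_config(fractions = cbind(f = 1, k = 2), n_post = 100,
                          noise = noise_off(), seed = 1)
  nc2 <- normalize_frap(simulate_frap_experiment(cfg2)$experiment)
  expect_equal(plateau(nc2), 1, tolerance = 0.02)

  # terminal window spanning all post frames = overall post mean
  expect_equal(plateau(nc2, terminal_window = 100),
               mean(nc2$values[6:105]))
})

test_that("population classification uses the t80 cutoff", {
  expect_identical(classify_population(list(t80_s = 8.1)), "fast")
  expect_identical(classify_population(list(t80_s = NA_real_, plateau = 0.65)),
                   "slow")
  expect_identical(classify_population(list(t80_s = 40)), "slow")
  expect_identical(classify_population(list(t80_s = 40),
                                       fast_t80_cutoff_s = 50), "fast")
})

test_that("fold over reference reproduces the kinetic summary ratios", {
  # nucleolar foci vs diffuse sensor
  expect_equal(round_half_up(fold_over_reference(135, 8), 3), 16.875)
  expect_equal(round_half_up(fold_over_reference(25, 2), 2), 12.5)
  # telomeric fast/slow vs the mean of the two binding-dead mutants
  expect_equal(round_half_up(fold_over_reference(8.1, c(2.4, 2.1)), 1), 3.6)
  expect_equal(round_half_up(fold_over_reference(40, c(2.4, 2.1)), 2), 17.78)
  expect_equal(round_half_up(fold_over_reference(1.5, c(0.6, 0.6)), 1), 2.5)
  expect_equal(round_half_up(fold_over_reference(4, c(0.6, 0.6)), 2), 6.67)

  # scale invariance in time units
  set.seed(1)
  for (rep in 1:20) {
    tgt <- runif(1, 0.1, 100)
    refs <- runif(sample(1:4, 1), 0.1, 100)
    s <- runif(1, 0.01, 50)
    expect_equal(fold_over_reference(tgt * s, refs * s),
                 fold_over_reference(tgt, refs), tolerance = 1e-12)
  }
  expect_error(fold_over_reference(-1, 2), "positive")
  expect_error(fold_over_reference(1, numeric()), "non-empty")
})

test_that("curve averaging and pointwise tests have closed-form behaviour", {
  cfg <- frap_sim_config(fractions = cbind(f = 1, k = 0.2),
                         noise = noise_off(), seed = 1)
  nc <- normalize_frap(simulate_frap_experiment(cfg)$experiment)
  m <- mean_curve_with_sd(list(nc, nc, nc))
  expect_true(all(m$sd == 0))
  expect_equal(m$mean, nc$values)

  a <- nc; a$values <- rep(0.4, length(nc$values))
  b <- nc; b$values <- rep(0.6, length(nc$values))
  m2 <- mean_curve_with_sd(list(a, b))
  expect_equal(unique(m2$mean), 0.5)
  expect_equal(unique(round(m2$sd, 6)), round(sqrt(0.02), 6))

  one <- mean_curve_with_sd(list(nc))
  expect_true(all(is.na(one$sd)))

  # n = 25 noisy curves: the mean tracks ground truth within 2 SE
  curves <- lapply(1:25, function(i) {
    normalize_frap(simulate_frap_experiment(
      frap_sim_config(fractions = cbind(f = 1, k = log(5) / 8.1),
                      seed = 100 + i))$experiment)
  })
  truth <- simulate_frap_experiment(
    frap_sim_config(fractions = cbind(f = 1, k = log(5) / 8.1),
                    noise = noise_off(), seed = 1))
  mm <- mean_curve_with_sd(curves)
  post <- 7:125  # skip the anchored frames
  se <- mm$sd[post] / sqrt(25)
  viol <- abs(mm$mean[post] - truth$truth$recovery[post - 5]) > 3 * se
  expect_lt(mean(viol), 0.05)
})

test_that("pointwise Welch t-curves match a direct oracle", {
  mk <- function(k, seed) normalize_frap(simulate_frap_experiment(
    frap_sim_config(fractions = cbind(f = 1, k = k), seed = seed))$experiment)
  ga <- lapply(1:6, function(i) mk(0.5, i))
  gb <- lapply(1:6, function(i) mk(0.5, 100 + i))
  same <- pointwise_ttest_curve(ga, ga)
  expect_true(all(same$p == 1))

  res <- pointwise_ttest_curve(ga, gb)
  # direct Welch oracle at an arbitrary frame
  f <- 40
  av <- vapply(ga, function(cu) cu$values[f], 0)
  bv <- vapply(gb, function(cu) cu$values[f], 0)
  tstat <- (mean(av) - mean(bv)) / sqrt(var(av) / 6 + var(bv) / 6)
  df <- (var(av) / 6 + var(bv) / 6)^2 /
    ((var(av) / 6)^2 / 5 + (var(bv) / 6)^2 / 5)
  expect_equal(res$p[f], 2 * pt(-abs(tstat), df), tolerance = 1e-12)

  # clearly separated groups: p < 0.001 at (almost) every post frame
  gfast <- lapply(1:20, function(i) mk(log(5) / 3, i))
  gslow <- lapply(1:20, function(i) mk(0.02, 200 + i))
  res2 <- pointwise_ttest_curve(gfast, gslow)
  expect_true(all(res2$p[10:125] < 0.001))
})

test_that("t50 recovery and classification meet the kinetic benchmarks", {
  set.seed(77)
  errs <- vapply(1:60, function(i) {
    k <- exp(runif(1, log(0.02), log(2)))
    sim <- simulate_frap_experiment(
      frap_sim_config(fractions = cbind(f = 1, k = k), seed = 5000 + i))
    t50 <- time_to_fraction(normalize_frap(sim$experiment), 0.5)
    abs(t50 - log(2) / k)
  }, 0)
  expect_lte(median(errs), 0.3)

  labs <- c(
    vapply(1:15, function(i) frap_kinetics(normalize_frap(
      simulate_frap_experiment(frap_sim_config(
        fractions = cbind(f = 1, k = log(5) / 8.1),
        seed = 300 + i))$experiment))$population, ""),
    vapply(1:10, function(i) frap_kinetics(normalize_frap(
      simulate_frap_experiment(frap_sim_config(
        fractions = cbind(f = 0.65, k = log(5) / 10),
        immobile_fraction = 0.35, seed = 400 + i))$experiment))$population, "")
  )
  expect_gte(mean(labs == rep(c("fast", "slow"), c(15, 10))), 0.95)
})
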