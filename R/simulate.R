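#' @keywords internal
#' Run expr with a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# camera chain shared by all simulators: photon means -> Poisson shot noise
# -> Gaussian read noise -> gain -> integer quantization (clipped to depth)
.camera <- function(photons, noise, quantize = TRUE) {
  x <- photons
  if (isTRUE(noise$poisson)) {
    x <- array(stats::rpois(length(x), lambda = as.vector(x)), dim = dim(photons))
  }
  if (noise$read_noise_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, noise$read_noise_sd)
  }
  x <- x * noise$gain
  if (quantize) x <- pmin(pmax(round(x), 0), 65535)
  x
}

#' Noise model settings for the synthetic camera
#' @param read_noise_sd Gaussian read noise standard deviation (applied
#'   before gain, photon-equivalent units).
#' @param gain counts per photon.
#' @param poisson apply Poisson shot noise.
#' @return list used by the simulators.
#' @export
noise_model <- function(read_noise_sd = 3, gain = 1, poisson = TRUE) {
  list(read_noise_sd = read_noise_sd, gain = gain, poisson = poisson)
}

#' @keywords internal
noise_off <- function() noise_model(read_noise_sd = 0, gain = 1, poisson = FALSE)

# add an anisotropic-Gaussian focus with the given peak amplitude
# (photons above the local level) to a (z, y, x) photon array; centers are
# 0-based voxel coordinates; returns the array with attr "total" set
.add_focus <- function(photons, center, sigma_vox, peak) {
  d <- dim(photons)
  sz <- sigma_vox["z"]; sy <- sigma_vox["y"]; sx <- sigma_vox["x"]
  rz <- ceiling(4 * sz); ry <- ceiling(4 * sy); rx <- ceiling(4 * sx)
  zz <- max(0, floor(center[3] - rz)):min(d[1] - 1, ceiling(center[3] + rz))
  yy <- max(0, floor(center[2] - ry)):min(d[2] - 1, ceiling(center[2] + ry))
  xx <- max(0, floor(center[1] - rx)):min(d[3] - 1, ceiling(center[1] + rx))
  gz <- exp(-((zz - center[3])^2) / (2 * sz^2))
  gy <- exp(-((yy - center[2])^2) / (2 * sy^2))
  gx <- exp(-((xx - center[1])^2) / (2 * sx^2))
  g <- peak * outer(outer(gz, gy), gx)     # (z, y, x) block
  photons[zz + 1L, yy + 1L, xx + 1L] <-
    photons[zz + 1L, yy + 1L, xx + 1L] + g
  attr(photons, "total") <- sum(g)
  photons
}

# 2D Gaussian blur (separable, mirror boundary); emulates the soft
# apparent boundary of diffuse structures in widefield/confocal images
.gauss_blur2d <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  w <- stats::dnorm(-r:r, sd = sigma_px)
  w <- w / sum(w)
  m <- .conv_sep(m, w, -r:r, along = "rows")
  .conv_sep(m, w, -r:r, along = "cols")
}

#' Scene configuration for the nuclear foci simulator
#'
#' Defaults emulate the targeted acquisition: ~30-slice 16-bit z-stacks,
#' 0.16 um pixels and 0.32 um z-steps, discrete PSF-blurred foci of
#' heterogeneous brightness over a low diffuse nuclear background, with
#' elevated nucleolar subregions and an extranuclear floor.
#'
#' @param image_shape (z, y, x) extents.
#' @param n_foci number of foci to place inside the nucleus.
#' @param focus_intensity_range (min, max) peak photons per focus above
#'   the local diffuse level, drawn uniformly (foci of heterogeneous
#'   brightness; the default keeps every focus at SNR >= ~11 under the
#'   default noise model).
#' @param focus_size_um (min, max) intrinsic focus radius (um), drawn
#'   uniformly and added in quadrature to the PSF width (foci of
#'   heterogeneous dimensions).
#' @param psf_sigma_um Gaussian PSF widths, `c(lateral, axial)` in um.
#' @param voxel_size_um named (z, y, x) voxel sizes in um.
#' @param nucleus `PolygonRoi`; default an octagon covering ~60% of the
#'   field.
#' @param nucleolus_regions list of `PolygonRoi` with elevated diffuse
#'   level.
#' @param diffuse_level nuclear diffuse sensor level (photons).
#' @param nucleolus_level diffuse level inside nucleolar regions (photons).
#' @param background_level extranuclear floor (photons).
#' @param noise camera noise settings from [noise_model()].
#' @param min_separation_px minimum lateral distance between placed foci.
#' @param edge_margin_px minimum distance of a focus from the nuclear
#'   polygon edge, keeping its PSF support in the nucleoplasm.
#' @param template_smooth_px Gaussian width (px) smoothing the
#'   background/diffuse/nucleolar template, emulating the soft apparent
#'   nuclear boundary at the optical resolution (default: the lateral PSF
#'   width).
#' @param seed RNG seed; all randomness in the scene flows from it.
#' @return a `SceneConfig` list.
#' @export
scene_config <- function(image_shape = c(z = 30L, y = 256L, x = 256L),
                         n_foci = 20L,
                         focus_intensity_range = c(120, 400),
                         focus_size_um = c(0, 0.10),
                         psf_sigma_um = c(lateral = 0.11, axial = 0.30),
                         voxel_size_um = c(z = 0.32, y = 0.16, x = 0.16),
                         nucleus = NULL,
                         nucleolus_regions = list(),
                         diffuse_level = 100,
                         nucleolus_level = 150,
                         background_level = 10,
                         noise = noise_model(),
                         min_separation_px = 8,
                         edge_margin_px = 10,
                         template_smooth_px = 0.7,
                         seed = 1L) {
  image_shape <- as.integer(image_shape)
  names(image_shape) <- c("z", "y", "x")
  if (is.null(nucleus)) {
    cy <- (image_shape["y"] - 1) / 2; cx <- (image_shape["x"] - 1) / 2
    r <- 0.42 * min(image_shape[c("y", "x")])
    th <- seq(0, 2 * pi, length.out = 9L)[-9L]
    nucleus <- polygon_roi(cbind(cx + r * cos(th), cy + r * sin(th)),
                           label = "nucleus")
  }
  stopifnot(n_foci >= 0, all(psf_sigma_um > 0),
            diffuse_level >= 0, background_level >= 0, nucleolus_level >= 0)
  structure(list(
    image_shape = image_shape, n_foci = as.integer(n_foci),
    focus_intensity_range = focus_intensity_range,
    focus_size_um = focus_size_um,
    psf_sigma_um = psf_sigma_um, voxel_size_um = voxel_size_um,
    nucleus = nucleus, nucleolus_regions = nucleolus_regions,
    diffuse_level = diffuse_level, nucleolus_level = nucleolus_level,
    background_level = background_level, noise = noise,
    min_separation_px = min_separation_px,
    edge_margin_px = edge_margin_px,
    template_smooth_px = template_smooth_px, seed = as.integer(seed)
  ), class = "SceneConfig")
}

#' Simulate a 3D nuclear scene with ground truth
#'
#' Builds the deterministic photon template (extranuclear floor, diffuse
#' nuclear level, elevated nucleoli, anisotropic-Gaussian foci placed
#' uniformly inside the nucleus with a minimum mutual distance), then
#' applies the camera chain Poisson -> Gaussian read -> gain -> quantize.
#'
#' @param config a `SceneConfig` from [scene_config()].
#' @return list with `stack` (16-bit (z, y, x) `ImageStack`) and `truth`
#'   (data frame of foci: 0-based centroid `x`, `y`, `z`, `total_photons`,
#'   `peak_photons`).
#' @export
simulate_nucleus_scene <- function(config) {
  stopifnot(inherits(config, "SceneConfig"))
  d <- config$image_shape
  nz <- d["z"]; ny <- d["y"]; nx <- d["x"]
  sigma_vox <- c(
    z = unname(config$psf_sigma_um["axial"] / config$voxel_size_um["z"]),
    y = unname(config$psf_sigma_um["lateral"] / config$voxel_size_um["y"]),
    x = unname(config$psf_sigma_um["lateral"] / config$voxel_size_um["x"])
  )
  nuc_mask <- roi_mask(config$nucleus, ny, nx)
  template2d <- matrix(config$background_level, ny, nx)
  template2d[nuc_mask] <- config$diffuse_level
  for (r in config$nucleolus_regions) {
    m <- roi_mask(r, ny, nx) & nuc_mask
    template2d[m] <- config$nucleolus_level
  }
  template2d <- .gauss_blur2d(template2d, config$template_smooth_px)
  photons <- aperm(array(rep(template2d, nz), dim = c(ny, nx, nz)), c(3, 1, 2))

  .with_seed(config$seed, {
    # place foci uniformly inside an eroded nucleus, min mutual distance;
    # the margin keeps each focus' PSF support clear of the bright nuclear
    # rim, whose step edge carries wavelet energy at all scales
    margin <- config$edge_margin_px
    placed <- matrix(numeric(0), ncol = 3)
    bb_x <- range(config$nucleus$vertices[, 1])
    bb_y <- range(config$nucleus$vertices[, 2])
    tries <- 0L
    while (nrow(placed) < config$n_foci) {
      tries <- tries + 1L
      if (tries > 20000L) {
        stop("focus placement impossible: nucleus too small for ",
             config$n_foci, " foci at the requested separation")
      }
      px <- stats::runif(1, bb_x[1] + margin, bb_x[2] - margin)
      py <- stats::runif(1, bb_y[1] + margin, bb_y[2] - margin)
      pz <- stats::runif(1, 2, nz - 3)
      if (!point_in_polygon(px, py, config$nucleus)) next
      # stay clear of the polygon edge so centroids are unambiguously inside
      if (!all(point_in_polygon(px + c(-margin, margin, 0, 0),
                                py + c(0, 0, -margin, margin),
                                config$nucleus))) next
      if (nrow(placed) &&
          min((placed[, 1] - px)^2 + (placed[, 2] - py)^2) <
            config$min_separation_px^2) next
      placed <- rbind(placed, c(px, py, pz))
    }
    peaks <- if (config$n_foci)
      stats::runif(config$n_foci, config$focus_intensity_range[1],
                   config$focus_intensity_range[2]) else numeric()
    sizes_um <- if (config$n_foci)
      stats::runif(config$n_foci, config$focus_size_um[1],
                   config$focus_size_um[2]) else numeric()
    totals <- numeric(config$n_foci)
    for (i in seq_len(config$n_foci)) {
      # intrinsic focus size adds to the PSF in quadrature
      sv <- sqrt(sigma_vox^2 +
                   (sizes_um[i] / config$voxel_size_um[c("z", "y", "x")])^2)
      names(sv) <- c("z", "y", "x")
      photons <- .add_focus(photons, placed[i, ], sv, peaks[i])
      totals[i] <- attr(photons, "total")
    }
    counts <- .camera(photons, config$noise)
    truth <- data.frame(
      x = if (config$n_foci) placed[, 1] else numeric(),
      y = if (config$n_foci) placed[, 2] else numeric(),
      z = if (config$n_foci) placed[, 3] else numeric(),
      total_photons = totals, peak_photons = peaks,
      size_um = sizes_um
    )
    list(
      stack = image_stack(counts, axes = c("z", "y", "x"),
                          voxel_size_um = config$voxel_size_um,
                          bit_depth = 16L),
      truth = truth
    )
  })
}

#' FRAP simulation configuration
#'
#' Defaults follow the short imaging protocol (5 pre-bleach and 120
#' post-bleach frames at 0.3 s); the long protocol uses 2 s intervals over
#' 126 s (58 post frames). Recovery is a sum of exponential exchange
#' components plus an immobile fraction (reaction-dominant binding, no
#' explicit spatial diffusion).
#'
#' @param fractions two-column matrix or data frame with columns `f`
#'   (amplitude) and `k` (rate, 1/s), one row per recovery component.
#' @param immobile_fraction fraction in `[0, 1)` that never recovers.
#' @param bleach_depth fraction of the ROI signal removed by the bleach,
#'   in `(0, 1]`.
#' @param n_pre,n_post frame counts before/after the bleach.
#' @param dt_s frame interval (s).
#' @param acquisition_bleach_rate per-frame multiplicative fluorescence
#'   loss from continuous imaging (e.g. 0.001 = 0.1%/frame).
#' @param roi_photons,reference_photons pre-bleach mean fluorescent photon
#'   levels in the bleach ROI and the reference (whole nucleus minus ROI).
#' @param background_photons non-fluorescent floor, common to all series.
#' @param npix_roi,npix_ref,npix_bg pixel counts behind each mean series
#'   (shot noise on a mean of n pixels scales as 1/sqrt(n)).
#' @param noise camera noise settings from [noise_model()].
#' @param seed RNG seed.
#' @return a `FrapSimConfig` list.
#' @export
frap_sim_config <- function(fractions = cbind(f = 1, k = log(2) / 2),
                            immobile_fraction = 0,
                            bleach_depth = 0.9,
                            n_pre = 5L, n_post = 120L, dt_s = 0.3,
                            acquisition_bleach_rate = 0.001,
                            roi_photons = 500,
                            reference_photons = 500,
                            background_photons = 50,
                            npix_roi = 490L, npix_ref = 4000L, npix_bg = 1000L,
                            noise = noise_model(),
                            seed = 1L) {
  fractions <- as.matrix(fractions)
  colnames(fractions) <- c("f", "k")
  if (any(fractions[, "k"] <= 0)) stop("recovery rates must be > 0")
  if (sum(fractions[, "f"]) + immobile_fraction > 1 + 1e-12) {
    stop("sum of component amplitudes plus immobile_fraction must be <= 1")
  }
  if (immobile_fraction < 0 || immobile_fraction >= 1) {
    stop("immobile_fraction must be in [0, 1)")
  }
  if (bleach_depth <= 0 || bleach_depth > 1) stop("bleach_depth must be in (0, 1]")
  if (n_pre < 1L || n_post < 1L) stop("need n_pre >= 1 and n_post >= 1")
  structure(list(
    fractions = fractions, immobile_fraction = immobile_fraction,
    bleach_depth = bleach_depth, n_pre = as.integer(n_pre),
    n_post = as.integer(n_post), dt_s = dt_s,
    acquisition_bleach_rate = acquisition_bleach_rate,
    roi_photons = roi_photons, reference_photons = reference_photons,
    background_photons = background_photons,
    npix_roi = npix_roi, npix_ref = npix_ref, npix_bg = npix_bg,
    noise = noise, seed = as.integer(seed)
  ), class = "FrapSimConfig")
}

# normalized ground-truth recovery: 0 at the first post-bleach frame,
# plateau sum(f)/(sum(f) + immobile)
.true_recovery <- function(config, t) {
  f <- config$fractions[, "f"]; k <- config$fractions[, "k"]
  S <- sum(f) + config$immobile_fraction
  colSums(f * (1 - exp(-outer(k, t)))) / S
}

#' Simulate a FRAP experiment (signal triple plus ground truth)
#'
#' Generates the three measured series (bleach-ROI mean, extracellular
#' background mean, reference mean) frame by frame: fluorescent levels
#' decay by `(1 - acquisition_bleach_rate)^frame`; after the bleach the ROI
#' level follows `floor + (1 - floor) * R(t)` with `floor = 1 -
#' bleach_depth` and `R` the multi-exponential ground-truth recovery. The
#' double normalization of [normalize_frap()] exactly inverts this
#' construction in the noise-free case.
#'
#' @param config a `FrapSimConfig` from [frap_sim_config()].
#' @return list with `experiment` (a `FrapExperiment`) and `truth` (list:
#'   `times_post_s`, `recovery` (noise-free normalized R at post frames),
#'   `plateau`, `t50_s`, `t80_s` — `NA` when never reached).
#' @export
simulate_frap_experiment <- function(config) {
  stopifnot(inherits(config, "FrapSimConfig"))
  n <- config$n_pre + config$n_post
  frames <- seq_len(n) - 1L
  times <- frames * config$dt_s
  decay <- (1 - config$acquisition_bleach_rate)^frames
  t_post <- (frames[(config$n_pre + 1L):n] - config$n_pre) * config$dt_s
  R <- .true_recovery(config, t_post)
  floor_ <- 1 - config$bleach_depth
  roi_level <- c(rep(1, config$n_pre), floor_ + (1 - floor_) * R)
  roi_mean <- config$background_photons + config$roi_photons * roi_level * decay
  ref_mean <- config$background_photons + config$reference_photons * decay
  bg_mean <- rep(config$background_photons, n)

  sim_mean <- function(mu, npix) {
    x <- mu * npix
    if (isTRUE(config$noise$poisson)) x <- stats::rpois(n, x)
    x <- x / npix
    if (config$noise$read_noise_sd > 0) {
      x <- x + stats::rnorm(n, 0, config$noise$read_noise_sd / sqrt(npix))
    }
    x * config$noise$gain
  }
  exp_ <- .with_seed(config$seed, {
    frap_experiment(
      times_s = times,
      roi_series = sim_mean(roi_mean, config$npix_roi),
      background_series = sim_mean(bg_mean, config$npix_bg),
      reference_series = sim_mean(ref_mean, config$npix_ref),
      n_pre = config$n_pre,
      bleach_roi = circle_roi(c(0, 0), 25)
    )
  })
  S <- sum(config$fractions[, "f"]) + config$immobile_fraction
  plateau_true <- sum(config$fractions[, "f"]) / S
  tt <- function(frac) {
    if (plateau_true <= frac) return(NA_real_)
    stats::uniroot(function(t) .true_recovery(config, t) - frac,
                   lower = 0, upper = 1e7, tol = 1e-10)$root
  }
  list(experiment = exp_,
       truth = list(times_post_s = t_post, recovery = R,
                    plateau = plateau_true,
                    t50_s = tt(0.5), t80_s = tt(0.8)))
}

#' Recovery components reproducing given crossing times
#'
#' Solves for a two-component exponential recovery (full mobility) whose
#' normalized curve crosses 0.5 at `t50_s` and 0.8 at `t80_s`. A single
#' exponential fixes t80/t50 = ln(5)/ln(2) ~ 2.32; measured populations
#' with larger ratios need (at least) two exchange components. The fast
#' amplitude is scanned over a grid and the rates solved by root finding.
#'
#' @param t50_s,t80_s target crossing times (s), `t80_s > t50_s` and
#'   `t80_s / t50_s > ln(5)/ln(2)`.
#' @return two-row `cbind(f, k)` matrix for [frap_sim_config()].
#' @export
frap_components_for_times <- function(t50_s, t80_s) {
  stopifnot(t80_s > t50_s)
  if (t80_s / t50_s <= log(5) / log(2) + 1e-9) {
    stop("t80/t50 <= ln(5)/ln(2): use a single exponential ",
         "(k = log(2)/t50_s)")
  }
  Rf <- function(t, f, k1, k2) f * (1 - exp(-k1 * t)) +
    (1 - f) * (1 - exp(-k2 * t))
  for (f in seq(0.5, 0.95, by = 0.05)) {
    g <- function(k2) {
      if ((1 - f) * (1 - exp(-k2 * t50_s)) >= 0.5) return(1)
      k1r <- stats::uniroot(function(k1) Rf(t50_s, f, k1, k2) - 0.5,
                            c(1e-9, 1e6), tol = 1e-13)$root
      Rf(t80_s, f, k1r, k2) - 0.8
    }
    k2r <- tryCatch(stats::uniroot(g, c(1e-7, 50), tol = 1e-13)$root,
                    error = function(e) NA_real_)
    if (is.na(k2r)) next
    k1r <- stats::uniroot(function(k1) Rf(t50_s, f, k1, k2r) - 0.5,
                          c(1e-9, 1e6), tol = 1e-13)$root
    return(cbind(f = c(f, 1 - f), k = c(k1r, k2r)))
  }
  stop("no two-component solution found for t50 = ", t50_s,
       ", t80 = ", t80_s)
}

#' Render a FRAP time-lapse movie with matching ROIs
#'
#' Builds a 2D+t image realization of a [frap_sim_config()] experiment: a
#' polygonal cell whose bleach-circle interior follows the ROI time course
#' and whose remainder follows the reference course, over a non-fluorescent
#' exterior. Useful for exercising frame registration and the ROI-mean
#' measurement path end to end.
#'
#' @param config a `FrapSimConfig`.
#' @param shape (y, x) frame extents.
#' @return list with `stack` (axes (t, y, x)), `bleach_roi`, `cell_roi`,
#'   `background_roi`, and `truth` as in [simulate_frap_experiment()].
#' @export
simulate_frap_movie <- function(config, shape = c(y = 96L, x = 96L)) {
  stopifnot(inherits(config, "FrapSimConfig"))
  ny <- shape[["y"]]; nx <- shape[["x"]]
  n <- config$n_pre + config$n_post
  frames <- seq_len(n) - 1L
  decay <- (1 - config$acquisition_bleach_rate)^frames
  t_post <- (frames[(config$n_pre + 1L):n] - config$n_pre) * config$dt_s
  R <- .true_recovery(config, t_post)
  floor_ <- 1 - config$bleach_depth
  roi_level <- c(rep(1, config$n_pre), floor_ + (1 - floor_) * R)

  cx <- nx * 0.45; cy <- ny * 0.5
  cell_r <- 0.36 * min(ny, nx)
  th <- seq(0, 2 * pi, length.out = 13L)[-13L]
  cell <- polygon_roi(cbind(cx + cell_r * cos(th), cy + cell_r * sin(th)),
                      label = "cell")
  bleach <- circle_roi(c(cx, cy), 25, label = "bleach")
  bg_poly <- polygon_roi(cbind(c(nx - 12, nx - 2, nx - 2, nx - 12),
                               c(2, 2, 12, 12)), label = "background")
  cell_m <- roi_mask(cell, ny, nx)
  bleach_m <- roi_mask(bleach, ny, nx) & cell_m
  arr <- array(0, dim = c(n, ny, nx))
  .with_seed(config$seed, {
    for (i in seq_len(n)) {
      ph <- matrix(config$background_photons, ny, nx)
      ph[cell_m] <- config$background_photons +
        config$reference_photons * decay[i]
      ph[bleach_m] <- config$background_photons +
        config$roi_photons * roi_level[i] * decay[i]
      arr[i, , ] <- .camera(ph, config$noise)
    }
  })
  S <- sum(config$fractions[, "f"]) + config$immobile_fraction
  list(
    stack = image_stack(arr, axes = c("t", "y", "x"),
                        voxel_size_um = c(y = 0.16, x = 0.16),
                        time_interval_s = config$dt_s, bit_depth = 16L),
    bleach_roi = bleach, cell_roi = cell, background_roi = bg_poly,
    truth = list(times_post_s = t_post, recovery = R,
                 plateau = sum(config$fractions[, "f"]) / S)
  )
}

#' Simulate a two-channel single-locus time lapse
#'
#' Channel 1 is a static locus marker spot; channel 2 is the sensor, whose
#' spot amplitude follows deterministic on/off transcription bursts (onsets
#' at `burst_period_s, 2 * burst_period_s, ...`). When `drb_time_s` is
#' given, bursting stops at that time and the sensor amplitude decays
#' exponentially with `drb_decay_tau_s` (default chosen so the signal is at
#' background ~30 min after treatment).
#'
#' @param burst_period_s burst onset spacing (s).
#' @param burst_duration_s burst length (s), must be `< burst_period_s`.
#' @param drb_time_s optional treatment time (s).
#' @param n_frames,dt_s frame count and interval (s).
#' @param drb_decay_tau_s exponential decay constant after treatment (s).
#' @param shape (z, y, x) extents.
#' @param marker_photons,sensor_photons peak photons of the marker spot
#'   and of the sensor spot during a burst.
#' @param diffuse_level,background_level photon floors inside/outside the
#'   nuclear area (the whole small field is treated as nuclear).
#' @param noise camera noise settings from [noise_model()].
#' @param seed RNG seed.
#' @return list with `stack` (axes (t, c, z, y, x); channel 1 marker,
#'   channel 2 sensor), and `truth` (list: `center` 0-based (x, y, z),
#'   `bursts` data frame of `(on_s, off_s)`, `sensor_amplitude` per frame).
#' @export
simulate_locus_timelapse <- function(burst_period_s = 45,
                                     burst_duration_s = 20,
                                     drb_time_s = NULL,
                                     n_frames = 75L, dt_s = 8,
                                     drb_decay_tau_s = 360,
                                     shape = c(z = 9L, y = 48L, x = 48L),
                                     marker_photons = 400,
                                     sensor_photons = 300,
                                     diffuse_level = 60,
                                     background_level = 60,
                                     noise = noise_model(),
                                     seed = 1L) {
  if (burst_duration_s >= burst_period_s) {
    stop("burst_duration_s must be < burst_period_s")
  }
  if (dt_s <= 0) stop("dt_s must be > 0")
  nz <- shape[["z"]]; ny <- shape[["y"]]; nx <- shape[["x"]]
  total_s <- n_frames * dt_s
  onsets <- seq(burst_period_s, by = burst_period_s,
                length.out = max(0, floor((total_s - 1e-9) / burst_period_s)))
  bursts <- data.frame(on_s = onsets,
                       off_s = pmin(onsets + burst_duration_s, total_s))
  center <- c(x = (nx - 1) / 2, y = (ny - 1) / 2, z = (nz - 1) / 2)
  sigma_vox <- c(z = 0.3 / 0.32, y = 0.11 / 0.16, x = 0.11 / 0.16)
  times <- (seq_len(n_frames) - 1L) * dt_s

  amp <- vapply(times, function(t) {
    if (!is.null(drb_time_s) && t >= drb_time_s) {
      # bursting stops; the standing signal decays to background
      return(exp(-(t - drb_time_s) / drb_decay_tau_s))
    }
    as.numeric(any(t >= bursts$on_s & t < bursts$off_s))
  }, 0)
  if (!is.null(drb_time_s)) {
    bursts <- bursts[bursts$on_s < drb_time_s, , drop = FALSE]
  }

  arr <- array(0, dim = c(n_frames, 2L, nz, ny, nx))
  .with_seed(seed, {
    for (i in seq_len(n_frames)) {
      ph_m <- array(background_level, dim = c(nz, ny, nx))
      ph_m <- .add_focus(ph_m, center[c("x", "y", "z")], sigma_vox,
                         marker_photons)
      ph_s <- array(diffuse_level, dim = c(nz, ny, nx))
      if (amp[i] > 0) {
        ph_s <- .add_focus(ph_s, center[c("x", "y", "z")], sigma_vox,
                           sensor_photons * amp[i])
      }
      arr[i, 1, , , ] <- .camera(ph_m, noise)
      arr[i, 2, , , ] <- .camera(ph_s, noise)
    }
  })
  list(
    stack = image_stack(arr, axes = c("t", "c", "z", "y", "x"),
                        voxel_size_um = c(z = 0.32, y = 0.16, x = 0.16),
                        time_interval_s = dt_s, bit_depth = 16L),
    truth = list(center = center, bursts = bursts, sensor_amplitude = amp,
                 times_s = times)
  )
}

#' Simulate a telomere/sensor two-channel cell
#'
#' Places `n_telomeres` marker foci inside a nuclear polygon; a chosen
#' subset additionally carries sensor signal at `sensor_contrast` times the
#' diffuse sensor background, emulating the above-background telomere
#' scoring setup.
#'
#' @param n_telomeres number of telomere marker foci.
#' @param n_with_sensor how many of them carry sensor accumulation.
#' @param sensor_contrast peak sensor level at positive telomeres, as a
#'   multiple of the diffuse background level.
#' @param image_shape (z, y, x) extents.
#' @param diffuse_level diffuse sensor photon level.
#' @param marker_photons peak photons per telomere marker focus.
#' @param noise camera noise settings.
#' @param seed RNG seed.
#' @return list with `marker` and `sensor` `ImageStack`s, `background_roi`
#'   (sensor-quiet nucleoplasmic polygon), `nucleus_roi` (a detection
#'   polygon drawn inside the nuclear rim), and `truth` (foci data frame
#'   with `has_sensor`).
#' @export
simulate_telomere_scene <- function(n_telomeres = 100L,
                                    n_with_sensor = 32L,
                                    sensor_contrast = 10,
                                    image_shape = c(z = 12L, y = 192L, x = 192L),
                                    diffuse_level = 50,
                                    marker_photons = 300,
                                    noise = noise_model(),
                                    seed = 1L) {
  stopifnot(n_with_sensor <= n_telomeres)
  cfg <- scene_config(image_shape = image_shape, n_foci = n_telomeres,
                      focus_intensity_range = c(marker_photons, marker_photons),
                      focus_size_um = c(0, 0),  # compact, diffraction-limited
                      diffuse_level = diffuse_level,
                      nucleolus_level = diffuse_level,
                      background_level = diffuse_level / 5,
                      noise = noise, min_separation_px = 7, seed = seed)
  marker <- simulate_nucleus_scene(cfg)
  truth <- marker$truth
  truth$has_sensor <- seq_len(n_telomeres) %in% seq_len(n_with_sensor)

  d <- cfg$image_shape
  sigma_vox <- c(z = 0.3 / cfg$voxel_size_um["z"],
                 y = 0.11 / cfg$voxel_size_um["y"],
                 x = 0.11 / cfg$voxel_size_um["x"])
  names(sigma_vox) <- c("z", "y", "x")
  ph <- array(diffuse_level, dim = d)
  peak <- (sensor_contrast - 1) * diffuse_level
  for (i in which(truth$has_sensor)) {
    ph <- .add_focus(ph, c(truth$x[i], truth$y[i], truth$z[i]),
                     sigma_vox, peak)
  }
  sensor_counts <- .with_seed(seed + 1L, .camera(ph, noise))
  sensor <- image_stack(sensor_counts, axes = c("z", "y", "x"),
                        voxel_size_um = cfg$voxel_size_um, bit_depth = 16L)
  # sensor-quiet background square near the nucleus centre, clear of foci
  ny <- d["y"]; nx <- d["x"]
  sq <- .find_quiet_square(truth, ny, nx, cfg$nucleus, half = 6)
  bg <- polygon_roi(cbind(c(sq[1] - 6, sq[1] + 6, sq[1] + 6, sq[1] - 6),
                          c(sq[2] - 6, sq[2] - 6, sq[2] + 6, sq[2] + 6)),
                    label = "nucleoplasm background")
  list(marker = marker$stack, sensor = sensor, background_roi = bg,
       nucleus_roi = shrink_polygon(cfg$nucleus, 6),
       truth = truth)
}

# deterministic scan for a nuclear square away from every focus; relaxes
# the clearance before giving up
.find_quiet_square <- function(truth, ny, nx, nucleus, half = 6) {
  for (clear in c(12, 10, 8)) {
    for (gy in seq(16, ny - 16, by = 2)) {
      for (gx in seq(16, nx - 16, by = 2)) {
        corners_x <- gx + c(-half, half, half, -half)
        corners_y <- gy + c(-half, -half, half, half)
        if (!all(point_in_polygon(corners_x, corners_y, nucleus))) next
        if (nrow(truth) &&
            min((truth$x - gx)^2 + (truth$y - gy)^2) < clear^2) next
        return(c(gx, gy))
      }
    }
  }
  stop("no sensor-quiet nucleoplasmic region found")
}
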