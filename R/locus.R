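#' Segment marker foci (e.g. telomeres) in 3D
#'
#' Runs the wavelet spot detector on the marker channel and returns each
#' retained component with its voxel set, ready for per-object sensor
#' intensity measurement.
#'
#' @param marker single-channel (z, y, x) `ImageStack`.
#' @param settings a `WaveletSettings`.
#' @param nucleus optional `PolygonRoi` restricting segmentation.
#' @return data frame (one row per object): `id`, centroid `x`, `y`, `z`
#'   (0-based), `n_voxels`, `mean_marker_intensity`, and a `voxels` list
#'   column of linear indices into the (z, y, x) array.
#' @export
segment_marker_foci <- function(marker, settings = wavelet_settings(),
                                nucleus = NULL) {
  spots <- detect_spots(marker, settings, nucleus = nucleus,
                        keep_voxels = TRUE)
  data.frame(
    id = seq_len(nrow(spots)),
    x = spots$x, y = spots$y, z = spots$z,
    n_voxels = spots$n_voxels,
    mean_marker_intensity = spots$mean_intensity,
    voxels = I(spots$voxels)
  )
}

#' Fraction of segmented objects with sensor signal above background
#'
#' For each object the mean sensor intensity over its voxels is compared
#' with the diffuse background measured in a nucleoplasmic ROI; an object
#' is above background when its mean exceeds
#' `bg_mean + k_sd * bg_sd`.
#'
#' @param objects data frame from [segment_marker_foci()] (needs the
#'   `voxels` list column).
#' @param sensor (z, y, x) `ImageStack` of the sensor channel.
#' @param background_roi `PolygonRoi` over diffuse nucleoplasm, away from
#'   the objects.
#' @param k_sd threshold margin in background SDs (default 2).
#' @return list with `fraction` (`NA` when there are no objects),
#'   `n_above`, `n_total`, `bg_mean`, `bg_sd`, and `objects` (input with
#'   `mean_sensor_intensity` and `above_background` columns added).
#' @export
fraction_above_background <- function(objects, sensor, background_roi,
                                      k_sd = 2) {
  stopifnot(inherits(sensor, "ImageStack"))
  arr <- sensor$data
  d <- dim(arr)
  if (nrow(objects) == 0L) {
    return(list(fraction = NA_real_, n_above = 0L, n_total = 0L,
                bg_mean = NA_real_, bg_sd = NA_real_, objects = objects))
  }
  m <- roi_mask(background_roi, d[2], d[3])
  zs <- roi_z_indices(background_roi, d[1])
  bg_vals <- unlist(lapply(zs, function(z) matrix(arr[z, , ], d[2], d[3])[m]))
  bg_mean <- mean(bg_vals); bg_sd <- stats::sd(bg_vals)
  sens <- vapply(objects$voxels, function(v) mean(arr[v]), 0)
  above <- if (is.infinite(k_sd)) rep(FALSE, length(sens))
           else sens > bg_mean + k_sd * bg_sd
  objects$mean_sensor_intensity <- sens
  objects$above_background <- above
  list(fraction = sum(above) / length(above),
       n_above = sum(above), n_total = length(above),
       bg_mean = bg_mean, bg_sd = bg_sd, objects = objects)
}

#' Intensity profile along a line segment
#'
#' Bilinear interpolation sampled at unit-pixel spacing from `p0` to `p1`
#' (0-based pixel coordinates), per channel.
#'
#' @param stack `ImageStack` with axes (y, x) or (c, y, x).
#' @param p0,p1 `(x, y)` endpoints.
#' @param channels 1-based channel indices (ignored for single-channel
#'   input).
#' @return data frame with `distance_px`, `x`, `y` and one `ch<i>` column
#'   per channel.
#' @export
line_profile <- function(stack, p0, p1, channels = NULL) {
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("zero-length segment")
  dist <- seq(0, floor(len))           # unit-pixel spacing
  tfrac <- dist / len
  xs <- p0[1] + (p1[1] - p0[1]) * tfrac
  ys <- p0[2] + (p1[2] - p0[2]) * tfrac
  has_c <- "c" %in% stack$axes
  if (is.null(channels)) {
    channels <- if (has_c) seq_len(dim(stack$data)[axis_index(stack, "c")]) else 1L
  }
  out <- data.frame(distance_px = dist, x = xs, y = ys)
  for (ch in channels) {
    plane <- if (has_c) slice_axis(stack, "c", ch) else stack$data
    plane <- matrix(plane, dim(plane)[1], dim(plane)[2])
    out[[paste0("ch", ch)]] <- .bilinear(plane, xs, ys)
  }
  out
}

# bilinear sample of a (y, x) matrix at 0-based (x, y) positions
.bilinear <- function(m, xs, ys) {
  ny <- nrow(m); nx <- ncol(m)
  x0 <- pmin(pmax(floor(xs), 0), nx - 1L)
  y0 <- pmin(pmax(floor(ys), 0), ny - 1L)
  x1 <- pmin(x0 + 1L, nx - 1L)
  y1 <- pmin(y0 + 1L, ny - 1L)
  fx <- xs - x0; fy <- ys - y0
  v00 <- m[cbind(y0 + 1L, x0 + 1L)]
  v01 <- m[cbind(y0 + 1L, x1 + 1L)]
  v10 <- m[cbind(y1 + 1L, x0 + 1L)]
  v11 <- m[cbind(y1 + 1L, x1 + 1L)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Track a single locus by center of intensity
#'
#' Per frame, the background-subtracted intensity-weighted 3D centroid of
#' the marker channel is computed within a search box around the previous
#' position; the sensor readout is the mean sensor intensity in a sphere
#' of `measure_radius_px` at that centroid minus the local background
#' (median of a surrounding shell), absorbing slow photobleaching.
#'
#' @param timelapse `ImageStack` with axes (t, c, z, y, x).
#' @param marker_channel,sensor_channel 1-based channel indices.
#' @param init_xy `(x, y)` 0-based position near the locus in frame 1.
#' @param search_radius_px lateral half-width of the search box.
#' @param measure_radius_px radius of the sensor measurement sphere.
#' @param shell_px `c(inner, outer)` extra radii of the background shell.
#' @return data frame of class `LocusTrack`: `time_s`, `x`, `y`, `z`,
#'   `marker`, `sensor`, `lost` (marker not found; position carried
#'   forward).
#' @export
track_locus <- function(timelapse, marker_channel = 1L, sensor_channel = 2L,
                        init_xy, search_radius_px = 5L,
                        measure_radius_px = 3L, shell_px = c(2L, 4L)) {
  stopifnot(identical(timelapse$axes, c("t", "c", "z", "y", "x")))
  d <- dim(timelapse$data)
  nt <- d[1]; nz <- d[3]; ny <- d[4]; nx <- d[5]
  dt <- if (!is.null(timelapse$time_interval_s)) timelapse$time_interval_s else 1
  init_xy <- unname(as.numeric(init_xy))
  pos <- c(x = init_xy[1], y = init_xy[2], z = (nz - 1) / 2)
  res <- data.frame(time_s = (seq_len(nt) - 1) * dt,
                    x = NA_real_, y = NA_real_, z = NA_real_,
                    marker = NA_real_, sensor = NA_real_, lost = FALSE)
  r <- search_radius_px
  for (i in seq_len(nt)) {
    mk <- array(timelapse$data[i, marker_channel, , , ], dim = c(nz, ny, nx))
    sn <- array(timelapse$data[i, sensor_channel, , , ], dim = c(nz, ny, nx))
    xs <- max(0, round(pos["x"]) - r):min(nx - 1, round(pos["x"]) + r)
    ys <- max(0, round(pos["y"]) - r):min(ny - 1, round(pos["y"]) + r)
    zs <- 0:(nz - 1)
    box <- mk[zs + 1L, ys + 1L, xs + 1L, drop = FALSE]
    bg <- stats::median(box)
    w <- box - bg
    w[w < 0] <- 0
    if (sum(w) == 0) {
      res$lost[i] <- TRUE
    } else {
      gz <- array(rep(zs, times = length(ys) * length(xs)), dim = dim(box))
      gy <- array(rep(rep(ys, each = length(zs)), times = length(xs)),
                  dim = dim(box))
      gx <- array(rep(xs, each = length(zs) * length(ys)), dim = dim(box))
      pos <- c(x = sum(gx * w) / sum(w),
               y = sum(gy * w) / sum(w),
               z = sum(gz * w) / sum(w))
    }
    res$x[i] <- pos["x"]; res$y[i] <- pos["y"]; res$z[i] <- pos["z"]
    sph <- .sphere_values(sn, pos, measure_radius_px)
    shell <- .shell_values(sn, pos, measure_radius_px + shell_px[1],
                           measure_radius_px + shell_px[2])
    res$marker[i] <- mean(.sphere_values(mk, pos, measure_radius_px)) -
      stats::median(.shell_values(mk, pos, measure_radius_px + shell_px[1],
                                  measure_radius_px + shell_px[2]))
    res$sensor[i] <- mean(sph) - stats::median(shell)
  }
  class(res) <- c("LocusTrack", class(res))
  res
}

# voxel values within a (possibly anisotropy-ignorant) sphere of radius r
# around a 0-based (x, y, z) position
.sphere_values <- function(arr, pos, r) {
  d <- dim(arr)
  zs <- max(0, floor(pos["z"] - r)):min(d[1] - 1, ceiling(pos["z"] + r))
  ys <- max(0, floor(pos["y"] - r)):min(d[2] - 1, ceiling(pos["y"] + r))
  xs <- max(0, floor(pos["x"] - r)):min(d[3] - 1, ceiling(pos["x"] + r))
  dist2 <- outer(outer((zs - pos["z"])^2, (ys - pos["y"])^2, `+`),
                 (xs - pos["x"])^2, `+`)
  block <- arr[zs + 1L, ys + 1L, xs + 1L, drop = FALSE]
  block[dist2 <= r^2]
}

.shell_values <- function(arr, pos, r_in, r_out) {
  d <- dim(arr)
  zs <- max(0, floor(pos["z"] - r_out)):min(d[1] - 1, ceiling(pos["z"] + r_out))
  ys <- max(0, floor(pos["y"] - r_out)):min(d[2] - 1, ceiling(pos["y"] + r_out))
  xs <- max(0, floor(pos["x"] - r_out)):min(d[3] - 1, ceiling(pos["x"] + r_out))
  dist2 <- outer(outer((zs - pos["z"])^2, (ys - pos["y"])^2, `+`),
                 (xs - pos["x"])^2, `+`)
  block <- arr[zs + 1L, ys + 1L, xs + 1L, drop = FALSE]
  block[dist2 > r_in^2 & dist2 <= r_out^2]
}

#' Detect intensity fluctuation cycles in a locus track
#'
#' Centered moving-average smoothing, then local maxima whose prominence
#' is at least `min_prominence` times the series SD; the median inter-peak
#' interval is the reported period.
#'
#' @param track a `LocusTrack` (or any data frame with `time_s` and
#'   `sensor`).
#' @param smooth_window odd moving-average window (frames); 1 = none.
#' @param min_prominence prominence threshold in series-SD units.
#' @return list with `peak_times_s`, `n_peaks`, `median_period_s` (`NA`
#'   with fewer than 2 peaks).
#' @export
detect_fluctuation_cycles <- function(track, smooth_window = 3L,
                                      min_prominence = 0.5) {
  v <- track$sensor
  t <- track$time_s
  if (length(v) < 3L) stop("need at least 3 frames")
  if (smooth_window >= 3L) {
    sm <- stats::filter(v, rep(1 / smooth_window, smooth_window), sides = 2)
    v[!is.na(sm)] <- sm[!is.na(sm)]
  }
  s <- stats::sd(v)
  if (is.na(s) || s == 0) {
    return(list(peak_times_s = numeric(), n_peaks = 0L,
                median_period_s = NA_real_))
  }
  n <- length(v)
  is_peak <- which(vapply(2:(n - 1), function(i) {
    v[i] > v[i - 1] && v[i] >= v[i + 1]
  }, TRUE)) + 1L
  keep <- vapply(is_peak, function(i) {
    left_min <- min(v[1:i])
    right_min <- min(v[i:n])
    prom <- v[i] - max(left_min, right_min)
    prom >= min_prominence * s
  }, TRUE)
  peaks <- is_peak[keep]
  list(peak_times_s = t[peaks], n_peaks = length(peaks),
       median_period_s = if (length(peaks) >= 2L)
         stats::median(diff(t[peaks])) else NA_real_)
}

#' Treatment-response p-value series
#'
#' Welch two-sided t-tests comparing the per-cell intensities at the time
#' point before treatment with the per-cell intensities at each time point
#' after treatment (and after washout).
#'
#' @param pre_values per-cell intensities before treatment (>= 2 cells).
#' @param post_series matrix (cells x time points) or data frame of
#'   per-cell intensity series after treatment.
#' @return data frame with `time_index` and `p`.
#' @export
treatment_response_test <- function(pre_values, post_series) {
  post_series <- as.matrix(post_series)
  if (length(pre_values) < 2L || nrow(post_series) < 2L) {
    stop("need at least 2 cells per comparison; ",
         "for a single cell use a paired design across frames instead")
  }
  p <- vapply(seq_len(ncol(post_series)), function(j) {
    a <- pre_values; b <- post_series[, j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    stats::t.test(a, b, var.equal = FALSE)$p.value
  }, 0)
  data.frame(time_index = seq_len(ncol(post_series)), p = p)
}
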