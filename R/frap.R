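#' FRAP measurement triple
#'
#' The three per-frame measurements of a FRAP experiment: mean intensity in
#' the bleached ROI, mean background intensity outside the cell, and mean
#' intensity of the labelled nucleus excluding the bleach ROI (the
#' reference used to compensate for acquisition photobleaching).
#'
#' @param times_s frame times in seconds, 0 at the first frame, strictly
#'   increasing.
#' @param roi_series,background_series,reference_series numeric series of
#'   equal length.
#' @param n_pre number of pre-bleach frames (>= 1, < series length).
#' @param bleach_roi the `CircleRoi` that was bleached.
#' @return an object of class `FrapExperiment`.
#' @export
frap_experiment <- function(times_s, roi_series, background_series,
                            reference_series, n_pre, bleach_roi = NULL) {
  n <- length(times_s)
  if (length(roi_series) != n || length(background_series) != n ||
      length(reference_series) != n) {
    stop("all series must have the same length as times_s")
  }
  if (any(diff(times_s) <= 0)) stop("times_s must be strictly increasing")
  if (n_pre < 1L || n_pre >= n) stop("need 1 <= n_pre < number of frames")
  structure(list(times_s = times_s, roi_series = roi_series,
                 background_series = background_series,
                 reference_series = reference_series,
                 n_pre = as.integer(n_pre), bleach_roi = bleach_roi),
            class = "FrapExperiment")
}

#' Align a time lapse by translation-only cross-correlation
#'
#' Each frame is shifted by the integer `(dx, dy)` maximizing its
#' cross-correlation with the first pre-bleach frame, searched over a
#' square radius. Constant (degenerate) frames get zero shift with a
#' warning.
#'
#' @param timelapse `ImageStack` with axes (t, y, x).
#' @param search_radius_px maximum |shift| searched per axis.
#' @return list with `stack` (registered `ImageStack`) and `shifts`
#'   (data frame `dx`, `dy` per frame, the shift *applied* to align).
#' @export
register_frames <- function(timelapse, search_radius_px = 8L) {
  stopifnot(identical(timelapse$axes, c("t", "y", "x")))
  arr <- timelapse$data
  nt <- dim(arr)[1]; ny <- dim(arr)[2]; nx <- dim(arr)[3]
  ref <- matrix(arr[1, , ], ny, nx)
  ref_c <- ref - mean(ref)
  r <- search_radius_px
  out <- arr
  shifts <- matrix(0L, nt, 2)
  degenerate <- FALSE
  for (i in seq_len(nt)) {
    fr <- matrix(arr[i, , ], ny, nx)
    if (stats::sd(fr) == 0 || stats::sd(ref) == 0) {
      degenerate <- TRUE
      next
    }
    best <- c(0L, 0L); best_cc <- -Inf
    for (dy in -r:r) {
      ys_r <- max(1, 1 + dy):min(ny, ny + dy)
      ys_f <- ys_r - dy
      for (dx in -r:r) {
        xs_r <- max(1, 1 + dx):min(nx, nx + dx)
        xs_f <- xs_r - dx
        a <- ref_c[ys_r, xs_r]
        b <- fr[ys_f, xs_f]
        cc <- sum(a * (b - mean(b)))
        denom <- sqrt(sum(a^2) * sum((b - mean(b))^2))
        cc <- if (denom > 0) cc / denom else -Inf
        if (cc > best_cc) { best_cc <- cc; best <- c(dx, dy) }
      }
    }
    shifts[i, ] <- best
    if (any(best != 0L)) {
      shifted <- matrix(0, ny, nx)
      ys_t <- max(1, 1 + best[2]):min(ny, ny + best[2])
      xs_t <- max(1, 1 + best[1]):min(nx, nx + best[1])
      shifted[ys_t, xs_t] <- fr[ys_t - best[2], xs_t - best[1]]
      out[i, , ] <- shifted
    }
  }
  if (degenerate) warning("constant frame(s): zero shift assumed")
  list(stack = image_stack(out, axes = timelapse$axes,
                           voxel_size_um = timelapse$voxel_size_um,
                           time_interval_s = timelapse$time_interval_s,
                           bit_depth = timelapse$bit_depth),
       shifts = data.frame(dx = shifts[, 1], dy = shifts[, 2]))
}

#' Extract the FRAP measurement triple from a registered time lapse
#'
#' @param timelapse `ImageStack` with axes (t, y, x).
#' @param bleach_roi `CircleRoi` of the bleached region.
#' @param cell_roi `PolygonRoi` around the labelled nucleus; the reference
#'   series is its mean excluding bleach-ROI pixels.
#' @param background_roi `PolygonRoi` outside the cell; must not overlap
#'   the cell ROI.
#' @param n_pre number of pre-bleach frames.
#' @return a `FrapExperiment`.
#' @export
measure_frap_signals <- function(timelapse, bleach_roi, cell_roi,
                                 background_roi, n_pre) {
  stopifnot(identical(timelapse$axes, c("t", "y", "x")))
  nt <- dim(timelapse$data)[1]
  ny <- dim(timelapse$data)[2]; nx <- dim(timelapse$data)[3]
  m_bleach <- roi_mask(bleach_roi, ny, nx)
  m_cell <- roi_mask(cell_roi, ny, nx)
  m_bg <- roi_mask(background_roi, ny, nx)
  if (any(m_bg & m_cell)) stop("background ROI overlaps the cell ROI")
  m_ref <- m_cell & !m_bleach
  roi_s <- bg_s <- ref_s <- numeric(nt)
  for (i in seq_len(nt)) {
    fr <- matrix(timelapse$data[i, , ], ny, nx)
    roi_s[i] <- mean(fr[m_bleach])
    bg_s[i] <- mean(fr[m_bg])
    ref_s[i] <- mean(fr[m_ref])
  }
  dt <- if (!is.null(timelapse$time_interval_s)) timelapse$time_interval_s else 1
  frap_experiment(times_s = (seq_len(nt) - 1L) * dt,
                  roi_series = roi_s, background_series = bg_s,
                  reference_series = ref_s, n_pre = n_pre,
                  bleach_roi = bleach_roi)
}

#' Double normalization of a FRAP experiment
#'
#' Background is subtracted from the ROI and reference series; the
#' reference then corrects for acquisition photobleaching
#' (`c(t) = mean_pre(ref) / ref(t)`); finally the corrected ROI series is
#' scaled so that the pre-bleach mean is exactly 1 and the first
#' post-bleach value exactly 0.
#'
#' @param exp a `FrapExperiment`.
#' @return an object of class `NormalizedFrapCurve`: list with `times_s`,
#'   `values`, `n_pre`.
#' @export
normalize_frap <- function(exp) {
  stopifnot(inherits(exp, "FrapExperiment"))
  b <- exp$roi_series - exp$background_series
  r <- exp$reference_series - exp$background_series
  if (any(r <= 0)) {
    stop("reference minus background is not positive at every frame; ",
         "cannot correct for acquisition bleaching")
  }
  pre <- seq_len(exp$n_pre)
  corr <- mean(r[pre]) / r
  x <- b * corr
  x0 <- x[exp$n_pre + 1L]
  denom <- mean(x[pre]) - x0
  if (denom == 0) stop("degenerate bleach: pre-bleach mean equals first post-bleach value")
  values <- (x - x0) / denom
  structure(list(times_s = exp$times_s, values = values, n_pre = exp$n_pre),
            class = "NormalizedFrapCurve")
}

#' Time after bleach to reach a recovery fraction
#'
#' First time after the bleach at which the normalized curve reaches the
#' fraction (relative to the pre-bleach level 1.0), with linear
#' interpolation between the bracketing frames; reported relative to the
#' first post-bleach frame. `NA` when the fraction is never reached.
#' An optional centered moving average can smooth the curve first.
#'
#' @param curve a `NormalizedFrapCurve`.
#' @param fraction recovery fraction in (0, 1).
#' @param smooth_window odd window length for optional smoothing
#'   (0 = none, the default).
#' @return seconds, or `NA_real_`.
#' @export
time_to_fraction <- function(curve, fraction, smooth_window = 0L) {
  stopifnot(inherits(curve, "NormalizedFrapCurve"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  v <- curve$values
  if (smooth_window >= 3L) {
    k <- rep(1 / smooth_window, smooth_window)
    sm <- stats::filter(v, k, sides = 2)
    v[!is.na(sm)] <- sm[!is.na(sm)]
  }
  i0 <- curve$n_pre + 1L           # first post-bleach frame
  t0 <- curve$times_s[i0]
  post <- i0:length(v)
  hit <- post[v[post] >= fraction]
  if (!length(hit)) return(NA_real_)
  j <- hit[1]
  if (j == i0) return(0)
  tj <- curve$times_s[j]; tj1 <- curve$times_s[j - 1L]
  vj <- v[j]; vj1 <- v[j - 1L]
  tcross <- tj1 + (fraction - vj1) / (vj - vj1) * (tj - tj1)
  tcross - t0
}

#' Terminal plateau of a normalized FRAP curve
#' @param curve a `NormalizedFrapCurve`.
#' @param terminal_window number of terminal frames averaged (default 10;
#'   capped at the number of post-bleach frames).
#' @return mean of the last `terminal_window` values.
#' @export
plateau <- function(curve, terminal_window = 10L) {
  stopifnot(inherits(curve, "NormalizedFrapCurve"))
  n <- length(curve$values)
  n_post <- n - curve$n_pre
  w <- min(terminal_window, n_post)
  mean(curve$values[(n - w + 1L):n])
}

#' Kinetic summary of a normalized FRAP curve
#'
#' @param curve a `NormalizedFrapCurve`.
#' @param terminal_window frames for [plateau()].
#' @param fast_t80_cutoff_s cutoff for [classify_population()].
#' @param smooth_window smoothing for [time_to_fraction()].
#' @return list of class `FrapKinetics`: `t50_s`, `t80_s`, `plateau`,
#'   `population`.
#' @export
frap_kinetics <- function(curve, terminal_window = 10L,
                          fast_t80_cutoff_s = 36, smooth_window = 0L) {
  t50 <- time_to_fraction(curve, 0.5, smooth_window)
  t80 <- time_to_fraction(curve, 0.8, smooth_window)
  kin <- structure(list(t50_s = t50, t80_s = t80,
                        plateau = plateau(curve, terminal_window),
                        population = NA_character_),
                   class = "FrapKinetics")
  kin$population <- classify_population(kin, fast_t80_cutoff_s)
  kin
}

#' Classify a FRAP curve as fast or slow
#'
#' A curve belongs to the fast population when it reaches 80% recovery
#' within the cutoff (default 36 s, the short-protocol post-bleach window);
#' curves that recover more slowly — or never reach 80%, e.g. plateau near
#' 65% — are slow.
#'
#' @param kin a `FrapKinetics` (or list with `t80_s`).
#' @param fast_t80_cutoff_s cutoff in seconds.
#' @return `"fast"` or `"slow"`.
#' @export
classify_population <- function(kin, fast_t80_cutoff_s = 36) {
  t80 <- kin$t80_s
  if (!is.na(t80) && t80 <= fast_t80_cutoff_s) "fast" else "slow"
}

#' Recovery-time fold over a reference population
#'
#' Ratio of a population's time-to-fraction to the arithmetic mean of the
#' reference times (e.g. the two binding-dead sensor mutants, or diffuse
#' sensor molecules). Scale-invariant in time units.
#'
#' @param target_time_s recovery time of the population of interest (s).
#' @param reference_times_s recovery times of the reference population(s).
#' @return the fold, full precision.
#' @export
fold_over_reference <- function(target_time_s, reference_times_s) {
  if (!length(reference_times_s)) stop("reference times must be non-empty")
  if (target_time_s <= 0 || any(reference_times_s <= 0)) {
    stop("recovery times must be positive")
  }
  target_time_s / mean(reference_times_s)
}

#' Round half-up at a fixed number of decimals (display rule)
#' @param x numeric.
#' @param digits decimals.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Pointwise mean and SD over normalized FRAP curves
#'
#' Curves on different time bases are resampled onto the first curve's
#' base by linear interpolation.
#'
#' @param curves list of `NormalizedFrapCurve`.
#' @return list with `times_s`, `mean`, `sd` (`sd` is `NA` for a single
#'   curve), `n`.
#' @export
mean_curve_with_sd <- function(curves) {
  stopifnot(length(curves) >= 1L)
  tb <- curves[[1]]$times_s
  vals <- vapply(curves, function(cu) {
    if (identical(cu$times_s, tb)) cu$values
    else stats::approx(cu$times_s, cu$values, xout = tb, rule = 2)$y
  }, numeric(length(tb)))
  vals <- matrix(vals, nrow = length(tb))
  list(times_s = tb,
       mean = rowMeans(vals),
       sd = if (length(curves) >= 2L) apply(vals, 1, stats::sd)
            else rep(NA_real_, length(tb)),
       n = length(curves))
}

#' Pointwise Welch t-test between two groups of FRAP curves
#'
#' Two-sided two-sample (Welch) t-test at each shared time point; frames
#' where both groups are constant give p = 1 when the means agree and
#' p = 0 otherwise.
#'
#' @param group_a,group_b lists of `NormalizedFrapCurve` (>= 2 each),
#'   sharing the time base of the first curve of `group_a`.
#' @return data frame with `time_s` and `p`.
#' @export
pointwise_ttest_curve <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  tb <- group_a[[1]]$times_s
  get <- function(curves) {
    v <- vapply(curves, function(cu) {
      if (identical(cu$times_s, tb)) cu$values
      else stats::approx(cu$times_s, cu$values, xout = tb, rule = 2)$y
    }, numeric(length(tb)))
    matrix(v, nrow = length(tb))
  }
  A <- get(group_a); B <- get(group_b)
  p <- vapply(seq_along(tb), function(i) {
    a <- A[i, ]; b <- B[i, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    stats::t.test(a, b, var.equal = FALSE)$p.value
  }, 0)
  data.frame(time_s = tb, p = p)
}
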