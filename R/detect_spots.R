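#' Label 26-connected components in a 3D logical mask
#'
#' Hand-written breadth-first labelling (2D labellers do not cover the
#' anisotropic-voxel case where diagonal z-contact is common).
#'
#' @param mask logical array, dim (z, y, x).
#' @return integer array of the same dim; 0 = background, components
#'   numbered from 1.
#' @export
label_components_3d <- function(mask) {
  d <- dim(mask)
  if (length(d) != 3L) stop("mask must be a 3D array")
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  lab <- array(0L, dim = d)
  fg <- which(mask)
  if (!length(fg)) return(lab)
  # 26-neighbourhood linear-index offsets (valid away from borders)
  nb <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  nb <- nb[!(nb$dz == 0 & nb$dy == 0 & nb$dx == 0), ]
  current <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    current <- current + 1L
    queue <- seed
    lab[seed] <- current
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      v0 <- v - 1L
      iz <- v0 %% nz
      iy <- (v0 %/% nz) %% ny
      ix <- v0 %/% (nz * ny)
      zz <- iz + nb$dz; yy <- iy + nb$dy; xx <- ix + nb$dx
      ok <- zz >= 0 & zz < nz & yy >= 0 & yy < ny & xx >= 0 & xx < nx
      cand <- 1L + zz[ok] + nz * (yy[ok] + ny * xx[ok])
      cand <- cand[mask[cand] & lab[cand] == 0L]
      if (length(cand)) {
        lab[cand] <- current
        queue <- c(queue, cand)
      }
    }
  }
  lab
}

#' Detect 3D foci by multi-scale wavelet support
#'
#' Each z-slice is decomposed with the undecimated a-trous transform
#' ([atrous_decompose()]); a voxel is kept when its detail coefficient
#' exceeds the per-scale threshold at *every* enabled scale (intersection of
#' scale masks). Per-scale thresholds follow the sensitivity rule of
#' [threshold_details()], with the robust noise scale pooled over all
#' slices (noise is stationary across the stack); when the pooled MAD is
#' zero (noise-free images) the pooled standard deviation is used instead.
#' Kept voxels are grouped by 26-connectivity in 3D, components outside the
#' `[min_size_vox, max_size_vox]` band are discarded, and, if a nuclear ROI
#' is given, spots whose intensity-weighted centroid falls outside the
#' polygon in x-y or outside its z-range are removed.
#'
#' @param stack single-channel `ImageStack` with axes (z, y, x) (apply
#'   [mean_of_channels()] first if needed) or a 2D (y, x) stack.
#' @param settings a `WaveletSettings` object.
#' @param nucleus optional `PolygonRoi` restricting detections.
#' @param keep_voxels if `TRUE`, attach each spot's voxel linear indices
#'   (into the (z, y, x) array) as a list column.
#' @param stabilize_variance apply the Anscombe transform
#'   `2 * sqrt(x + 3/8)` to each plane before decomposition (default), so
#'   that Poisson shot noise is stationary across bright and dim regions
#'   and one pooled noise scale is valid; intensity statistics are always
#'   measured on the original stack.
#' @return data frame with one row per spot: `x`, `y`, `z` (0-based
#'   intensity-weighted centroid), `n_voxels`, `total_intensity`,
#'   `mean_intensity`, `scales`, `inside_nucleus`.
#' @export
detect_spots <- function(stack, settings = wavelet_settings(), nucleus = NULL,
                         keep_voxels = FALSE, stabilize_variance = TRUE) {
  stopifnot(inherits(stack, "ImageStack"))
  if ("c" %in% stack$axes || "t" %in% stack$axes) {
    stop("detect_spots needs a single-channel, single-timepoint stack")
  }
  arr <- stack$data
  if (identical(stack$axes, c("y", "x"))) {
    arr <- array(arr, dim = c(1L, dim(arr)))
  }
  d <- dim(arr)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  n_scales <- max(settings$enabled_scales)

  arrT <- if (stabilize_variance) 2 * sqrt(pmax(arr, 0) + 0.375) else arr
  decomp <- vector("list", nz)
  for (k in seq_len(nz)) {
    decomp[[k]] <- atrous_decompose(matrix(arrT[k, , ], ny, nx), n_scales)$details
  }
  # image noise estimated robustly from the first detail plane (pooled
  # over slices) and propagated to coarser scales through the kernel's
  # white-noise variance fractions; MAD of a coarse detail plane itself
  # would be inflated by real large-scale structure (nuclear rim, diffuse
  # plateau), masking dim diffraction-limited spots
  frac <- .atrous_noise_fractions(n_scales)
  pooled1 <- unlist(lapply(decomp, function(dd) as.vector(dd[[1]])))
  sigma_img <- stats::mad(pooled1) / frac[1]
  if (is.na(sigma_img)) sigma_img <- 0
  # stabilized counts carry unit shot noise by construction; quantization
  # ripple in noise-free synthetic images must not masquerade as the
  # noise floor, so the estimate is floored at the shot-noise level
  if (stabilize_variance) sigma_img <- max(sigma_img, 1)
  mask <- array(TRUE, dim = d)
  for (j in settings$enabled_scales) {
    tau <- (100 / settings$sensitivity_per_scale[[as.character(j)]]) * 3 *
      sigma_img * frac[j]
    for (k in seq_len(nz)) {
      mask[k, , ] <- mask[k, , ] & (decomp[[k]][[j]] > tau)
    }
  }

  lab <- label_components_3d(mask)
  n_comp <- max(lab)
  spots <- list()
  scales_str <- paste(settings$enabled_scales, collapse = ",")
  if (n_comp > 0) {
    idx <- which(lab > 0L)
    comp <- lab[idx]
    sizes <- tabulate(comp, nbins = n_comp)
    ord <- order(comp)
    idx <- idx[ord]; comp <- comp[ord]
    bounds <- c(0L, cumsum(sizes))
    for (ci in seq_len(n_comp)) {
      if (sizes[ci] < settings$min_size_vox || sizes[ci] > settings$max_size_vox) next
      vox <- idx[(bounds[ci] + 1L):bounds[ci + 1L]]
      v0 <- vox - 1L
      iz <- v0 %% nz
      iy <- (v0 %/% nz) %% ny
      ix <- v0 %/% (nz * ny)
      w <- arr[vox]
      tot <- sum(w)
      if (tot <= 0) w <- rep(1, length(vox))
      cx <- sum(ix * w) / sum(w)
      cy <- sum(iy * w) / sum(w)
      cz <- sum(iz * w) / sum(w)
      spots[[length(spots) + 1L]] <- list(
        x = cx, y = cy, z = cz, n_voxels = sizes[ci],
        total_intensity = tot, mean_intensity = tot / sizes[ci],
        scales = scales_str, voxels = vox)
    }
  }
  if (!length(spots)) {
    out <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      n_voxels = integer(), total_intensity = numeric(),
                      mean_intensity = numeric(), scales = character(),
                      inside_nucleus = logical())
    if (keep_voxels) out$voxels <- I(list())
    return(out)
  }
  out <- data.frame(
    x = vapply(spots, `[[`, 0, "x"),
    y = vapply(spots, `[[`, 0, "y"),
    z = vapply(spots, `[[`, 0, "z"),
    n_voxels = vapply(spots, `[[`, 0L, "n_voxels"),
    total_intensity = vapply(spots, `[[`, 0, "total_intensity"),
    mean_intensity = vapply(spots, `[[`, 0, "mean_intensity"),
    scales = vapply(spots, `[[`, "", "scales"),
    stringsAsFactors = FALSE
  )
  if (keep_voxels) out$voxels <- I(lapply(spots, `[[`, "voxels"))

  if (is.null(nucleus)) {
    out$inside_nucleus <- NA
  } else {
    in_xy <- point_in_polygon(out$x, out$y, nucleus)
    zr <- roi_z_indices(nucleus, nz) - 1L  # back to 0-based
    in_z <- out$z >= min(zr) & out$z <= max(zr)
    out$inside_nucleus <- in_xy & in_z
    out <- out[out$inside_nucleus, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Otsu threshold of a value vector (between-class variance maximization
# over a 256-bin histogram of the observed range)
.otsu_vec <- function(v, nbins = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu0)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Count foci per nucleus on maximum intensity projections
#'
#' Nuclei are segmented on the nuclear-stain projection (global Otsu
#' threshold, hole filling, minimum-area filter); foci are thresholded per
#' nucleus with Otsu computed on the nucleus' own foci-stain pixels, and
#' connected components with area strictly greater than `min_focus_size_px`
#' are counted.
#'
#' @param nuclear_stain,foci_stain `ImageStack`s sharing spatial extents;
#'   z-stacks are projected first.
#' @param min_focus_size_px foci smaller than or equal to this area (px)
#'   are ignored (default 3).
#' @param min_nucleus_area_px minimum segmented nucleus area (px).
#' @return data frame with `nucleus_id`, `area_px`, `n_foci`; zero rows
#'   (with a warning) when no nucleus is found.
#' @export
count_foci_per_nucleus <- function(nuclear_stain, foci_stain,
                                   min_focus_size_px = 3L,
                                   min_nucleus_area_px = 50L) {
  nuc <- if ("z" %in% nuclear_stain$axes) max_project(nuclear_stain) else nuclear_stain
  foc <- if ("z" %in% foci_stain$axes) max_project(foci_stain) else foci_stain
  nimg <- nuc$data / max(1, max(nuc$data))
  if (!identical(dim(nuc$data), dim(foc$data))) {
    stop("nuclear and foci stains must share spatial extents")
  }
  thr <- tryCatch(EBImage::otsu(EBImage::Image(t(nimg))),
                  error = function(e) NA_real_)
  if (is.na(thr) || max(nimg) == 0) {
    warning("no nucleus found")
    return(data.frame(nucleus_id = integer(), area_px = integer(),
                      n_foci = integer()))
  }
  nmask <- EBImage::fillHull(EBImage::Image(t(nimg) > thr))
  labels <- EBImage::bwlabel(nmask)
  lm <- t(EBImage::imageData(labels))  # back to (y, x)
  areas <- tabulate(lm[lm > 0])
  keep <- which(areas >= min_nucleus_area_px)
  if (!length(keep)) {
    warning("no nucleus found")
    return(data.frame(nucleus_id = integer(), area_px = integer(),
                      n_foci = integer()))
  }
  res <- lapply(seq_along(keep), function(i) {
    id <- keep[i]
    inside <- lm == id
    vals <- foc$data[inside]
    thr_f <- .otsu_vec(vals)
    fmask <- matrix(FALSE, nrow(lm), ncol(lm))
    fmask[inside] <- foc$data[inside] > thr_f
    flab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(fmask)))))
    fareas <- tabulate(flab[flab > 0])
    data.frame(nucleus_id = i, area_px = areas[id],
               n_foci = sum(fareas > min_focus_size_px))
  })
  do.call(rbind, res)
}
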