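#' Image stack with axis semantics
#'
#' An `ImageStack` wraps an n-dimensional voxel array together with ordered
#' axis labels drawn from `(t, c, z, y, x)`, the physical voxel sizes of the
#' spatial axes (micrometres), the frame interval of the time axis (seconds)
#' and the source bit depth. All package functions take and return stacks in
#' this canonical axis order, with missing axes omitted; voxel coordinates
#' reported to the user are 0-based, `(x, y)` being column/row pixel centers.
#'
#' @param data numeric or integer array; `dim(data)` must match `axes`.
#'   A plain matrix is interpreted as `(y, x)`.
#' @param axes character vector of axis labels, a subset of
#'   `c("t","c","z","y","x")` in that order.
#' @param voxel_size_um named numeric, physical size of each spatial axis
#'   present (`z`, `y`, `x`), in micrometres.
#' @param time_interval_s frame spacing in seconds; required only when a
#'   `t` axis is present.
#' @param bit_depth integer, 8 or 16; values must fit the declared depth
#'   when the stack is written to disk.
#'
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(data,
                        axes = NULL,
                        voxel_size_um = c(z = 0.32, y = 0.16, x = 0.16),
                        time_interval_s = NULL,
                        bit_depth = 16L) {
  if (is.matrix(data)) data <- array(data, dim = dim(data))
  if (!is.null(names(dim(data)))) dim(data) <- unname(dim(data))
  nd <- length(dim(data))
  if (is.null(axes)) {
    axes <- switch(as.character(nd),
      "2" = c("y", "x"),
      "3" = c("z", "y", "x"),
      "4" = c("c", "z", "y", "x"),
      "5" = c("t", "c", "z", "y", "x"),
      stop("cannot infer axes for a ", nd, "-dimensional array")
    )
  }
  canonical <- c("t", "c", "z", "y", "x")
  if (!all(axes %in% canonical)) {
    stop("unknown axis label(s): ", paste(setdiff(axes, canonical), collapse = ", "))
  }
  if (anyDuplicated(axes)) stop("axis labels must be unique")
  if (!identical(axes, canonical[canonical %in% axes])) {
    stop("axes must be ordered (t, c, z, y, x); got: ", paste(axes, collapse = ", "))
  }
  if (length(axes) != nd) {
    stop("length(axes) [", length(axes), "] does not match array rank [", nd, "]")
  }
  if (any(dim(data) < 1L)) stop("every axis extent must be >= 1")
  spatial <- intersect(axes, c("z", "y", "x"))
  vs <- voxel_size_um[spatial]
  if (any(is.na(vs)) || any(vs <= 0)) {
    stop("voxel_size_um must give a positive size for each spatial axis present")
  }
  if ("t" %in% axes && (is.null(time_interval_s) || time_interval_s <= 0)) {
    stop("time_interval_s must be a positive number when a t axis is present")
  }
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  structure(
    list(
      data = data,
      axes = axes,
      voxel_size_um = vs,
      time_interval_s = if ("t" %in% axes) time_interval_s else NULL,
      bit_depth = as.integer(bit_depth)
    ),
    class = "ImageStack"
  )
}

#' @export
print.ImageStack <- function(x, ...) {
  cat("<ImageStack> ", paste(sprintf("%s=%d", x$axes, dim(x$data)), collapse = " "),
      sprintf(" [%d-bit]\n", x$bit_depth))
  cat("  voxel size (um):", paste(sprintf("%s=%.3g", names(x$voxel_size_um),
                                          x$voxel_size_um), collapse = " "), "\n")
  if (!is.null(x$time_interval_s)) {
    cat("  frame interval (s):", x$time_interval_s, "\n")
  }
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$data)

axis_index <- function(stack, axis) {
  i <- match(axis, stack$axes)
  if (is.na(i)) stop("stack has no '", axis, "' axis")
  i
}

#' Extract one hyperplane along an axis, dropping that axis
#' @param stack an `ImageStack`
#' @param axis axis label
#' @param i 1-based index along that axis
#' @return array of rank one less than the stack
#' @keywords internal
slice_axis <- function(stack, axis, i) {
  ai <- axis_index(stack, axis)
  idx <- rep(list(quote(expr = )), length(stack$axes))
  idx[[ai]] <- i
  out <- do.call(`[`, c(list(stack$data), idx, list(drop = FALSE)))
  d <- dim(out)[-ai]
  array(out, dim = d)
}

#' Read a multi-page TIFF into an ImageStack
#'
#' Axis semantics are restored from the JSON sidecar written by
#' [write_stack()] when present; otherwise `axes_hint` is used to fold the
#' page sequence, and a bare multi-page file with neither is rejected as
#' ambiguous (pages could be z, t or c).
#'
#' @param path path to a TIFF file.
#' @param axes_hint optional character vector of axis labels; the non-(y,x)
#'   extents are inferred from the page count for a single unknown axis, or
#'   taken from the sidecar/hint attributes.
#' @param ... further arguments passed to [image_stack()] (voxel sizes etc.)
#'   when no sidecar is present.
#' @return an `ImageStack`.
#' @export
read_stack <- function(path, axes_hint = NULL, ...) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  npage <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  flat <- array(0, dim = c(ny, nx, npage))
  for (i in seq_len(npage)) flat[, , i] <- pages[[i]]

  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    axes <- meta$axes
    dims <- as.integer(meta$dim)
    stk <- .fold_pages(flat, axes, dims)
    return(image_stack(stk, axes = axes,
                       voxel_size_um = unlist(meta$voxel_size_um),
                       time_interval_s = meta$time_interval_s,
                       bit_depth = as.integer(meta$bit_depth)))
  }
  if (!is.null(axes_hint)) {
    extra <- setdiff(axes_hint, c("y", "x"))
    if (length(extra) > 1L) {
      stop("axes_hint with more than one non-spatial axis needs a sidecar ",
           "to disambiguate extents")
    }
    dims <- c(if (length(extra)) npage, ny, nx)
    return(image_stack(.fold_pages(flat, axes_hint, dims), axes = axes_hint, ...))
  }
  if (npage == 1L) {
    return(image_stack(array(flat, dim = c(ny, nx)), axes = c("y", "x"), ...))
  }
  stop("ambiguous dimensionality: ", npage, " pages could be axes (z,y,x), ",
       "(t,y,x) or (c,y,x); pass axes_hint or use a stack with a sidecar")
}

# Fold a (y, x, page) array into canonical axis order given target axes/dims.
# Pages enumerate the non-(y,x) axes with the LAST of them varying fastest
# (row-major page order, matching write_stack).
.fold_pages <- function(flat, axes, dims) {
  ny <- dim(flat)[1]; nx <- dim(flat)[2]; npage <- dim(flat)[3]
  lead <- setdiff(axes, c("y", "x"))
  lead_dims <- dims[seq_along(lead)]
  if (prod(lead_dims) * ny * nx != npage * ny * nx) {
    stop("page count ", npage, " does not match declared extents (",
         paste(lead_dims, collapse = "x"), ")")
  }
  out <- array(0, dim = dims)
  if (length(lead) == 0L) return(array(flat[, , 1], dim = c(ny, nx)))
  # page p (1-based) -> lead indices, last lead axis fastest
  for (p in seq_len(npage)) {
    rem <- p - 1L
    idx <- integer(length(lead))
    for (k in rev(seq_along(lead))) {
      idx[k] <- rem %% lead_dims[k]
      rem <- rem %/% lead_dims[k]
    }
    call_idx <- c(as.list(idx + 1L), list(quote(expr = ), quote(expr = )))
    out <- do.call(`[<-`, c(list(out), call_idx, list(value = flat[, , p])))
  }
  out
}

#' Write an ImageStack as a multi-page TIFF with a JSON sidecar
#'
#' Pages enumerate the non-(y,x) axes in canonical order with the innermost
#' axis varying fastest; axis labels, extents, voxel sizes and bit depth go
#' to `<path>.json` so that [read_stack()] restores the stack exactly.
#' Baseline uncompressed TIFF; round-trip is voxel-exact for unsigned
#' 8/16-bit data.
#'
#' @param stack an `ImageStack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  maxval <- 2^stack$bit_depth - 1
  if (min(stack$data) < 0 || max(stack$data) > maxval) {
    stop("voxel values do not fit the declared ", stack$bit_depth, "-bit depth")
  }
  d <- dim(stack$data)
  axes <- stack$axes
  lead <- setdiff(axes, c("y", "x"))
  lead_dims <- d[match(lead, axes)]
  ny <- d[match("y", axes)]; nx <- d[match("x", axes)]
  npage <- prod(c(1L, lead_dims))
  pages <- vector("list", npage)
  for (p in seq_len(npage)) {
    rem <- p - 1L
    idx <- integer(length(lead))
    if (length(lead)) {
      for (k in rev(seq_along(lead))) {
        idx[k] <- rem %% lead_dims[k]
        rem <- rem %/% lead_dims[k]
      }
    }
    call_idx <- c(as.list(idx + 1L), list(quote(expr = ), quote(expr = )))
    pg <- do.call(`[`, c(list(stack$data), call_idx, list(drop = FALSE)))
    pages[[p]] <- matrix(pg, ny, nx) / maxval
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                        compression = "none", reduce = FALSE)
  if (ok < 1L) stop("failed to write TIFF: ", path)
  meta <- list(
    axes = stack$axes,
    dim = d,
    voxel_size_um = as.list(stack$voxel_size_um),
    time_interval_s = stack$time_interval_s,
    bit_depth = stack$bit_depth
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Maximum intensity projection along z
#' @param stack an `ImageStack` with a `z` axis.
#' @return an `ImageStack` without the `z` axis.
#' @export
max_project <- function(stack) {
  zi <- axis_index(stack, "z")
  d <- dim(stack$data)
  keep <- setdiff(seq_along(d), zi)
  out <- apply(stack$data, keep, max)
  image_stack(array(out, dim = d[keep]), axes = stack$axes[-zi],
              voxel_size_um = stack$voxel_size_um[setdiff(names(stack$voxel_size_um), "z")],
              time_interval_s = stack$time_interval_s,
              bit_depth = stack$bit_depth)
}

#' Average the channel axis away
#'
#' Pre-processing step applied before spot detection on multi-channel
#' stacks: each voxel becomes the arithmetic mean over channels, in real
#' values (no re-quantization).
#'
#' @param stack an `ImageStack` with a `c` axis.
#' @return a single-channel `ImageStack` (real-valued voxels).
#' @export
mean_of_channels <- function(stack) {
  ci <- axis_index(stack, "c")
  d <- dim(stack$data)
  keep <- setdiff(seq_along(d), ci)
  out <- apply(stack$data, keep, mean)
  image_stack(array(out, dim = d[keep]), axes = stack$axes[-ci],
              voxel_size_um = stack$voxel_size_um,
              time_interval_s = stack$time_interval_s,
              bit_depth = stack$bit_depth)
}
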