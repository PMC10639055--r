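#' Polygon region of interest
#'
#' Vertices are `(x, y)` pixel-center coordinates (0-based, x = column,
#' y = row). The polygon must be simple (no self-intersection) and have at
#' least 3 vertices. `z_range` restricts the ROI to an inclusive 0-based
#' slice interval, or `"all"`.
#'
#' @param vertices two-column matrix (x, y) or list of `c(x, y)` pairs.
#' @param z_range `"all"` or `c(lo, hi)` inclusive 0-based slice indices.
#' @param label free-text label.
#' @return an object of class `PolygonRoi`.
#' @export
polygon_roi <- function(vertices, z_range = "all", label = "") {
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  vertices <- matrix(as.numeric(vertices), ncol = 2,
                     dimnames = list(NULL, c("x", "y")))
  if (nrow(vertices) < 3L) stop("a polygon ROI needs at least 3 vertices")
  if (.polygon_self_intersects(vertices)) {
    stop("polygon ROI is self-intersecting; only simple polygons are allowed")
  }
  if (!identical(z_range, "all")) {
    z_range <- as.numeric(z_range)
    if (length(z_range) != 2L || z_range[1] > z_range[2]) {
      stop("z_range must be \"all\" or c(lo, hi) with lo <= hi")
    }
  }
  structure(list(vertices = vertices, z_range = z_range, label = label),
            class = "PolygonRoi")
}

#' Circular region of interest
#'
#' @param center `(x, y)` pixel coordinates (0-based).
#' @param diameter_px positive diameter in pixels.
#' @param z_index 0-based slice index, or `"projection"`.
#' @param label free-text label.
#' @return an object of class `CircleRoi`.
#' @export
circle_roi <- function(center, diameter_px, z_index = "projection", label = "") {
  center <- as.numeric(center)
  if (length(center) != 2L) stop("center must be (x, y)")
  if (diameter_px < 1) stop("diameter_px must be >= 1")
  structure(list(center = c(x = center[1], y = center[2]),
                 diameter_px = as.numeric(diameter_px),
                 z_index = z_index, label = label),
            class = "CircleRoi")
}

# proper-intersection test between non-adjacent edges; shared endpoints of
# adjacent edges are not intersections
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Point-in-polygon test
#'
#' Even-odd (ray-casting) rule, vectorized over points; for simple polygons
#' this agrees with the winding-number rule. Points exactly on a horizontal
#' edge follow the half-open edge convention.
#'
#' @param px,py point coordinates (0-based pixel coordinates).
#' @param roi a `PolygonRoi`.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, roi) {
  v <- if (inherits(roi, "PolygonRoi")) roi$vertices else roi
  n <- nrow(v)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize an ROI to a logical (y, x) mask
#'
#' A pixel belongs to the mask when its center (0-based `(x, y)` =
#' (col-1, row-1)) lies inside the ROI.
#'
#' @param roi a `PolygonRoi` or `CircleRoi`.
#' @param ny,nx mask extents (rows, columns).
#' @return `ny` x `nx` logical matrix.
#' @export
roi_mask <- function(roi, ny, nx) {
  px <- rep(seq_len(nx) - 1L, each = ny)
  py <- rep(seq_len(ny) - 1L, times = nx)
  if (inherits(roi, "CircleRoi")) {
    r <- roi$diameter_px / 2
    inside <- (px - roi$center["x"])^2 + (py - roi$center["y"])^2 <= r^2
  } else {
    inside <- point_in_polygon(px, py, roi)
  }
  matrix(inside, ny, nx)
}

#' Shrink a polygon ROI toward its vertex centroid
#'
#' Moves every vertex radially toward the centroid by `by_px` pixels
#' (exact for star-shaped polygons; the analogue of drawing a nuclear ROI
#' just inside the fluorescence accumulation, clear of the rim).
#'
#' @param roi a `PolygonRoi`.
#' @param by_px shrink distance in pixels.
#' @return a `PolygonRoi`.
#' @export
shrink_polygon <- function(roi, by_px) {
  stopifnot(inherits(roi, "PolygonRoi"))
  v <- roi$vertices
  ctr <- colMeans(v)
  d <- sqrt((v[, 1] - ctr[1])^2 + (v[, 2] - ctr[2])^2)
  if (any(d <= by_px)) stop("polygon too small to shrink by ", by_px, " px")
  f <- (d - by_px) / d
  polygon_roi(cbind(ctr[1] + (v[, 1] - ctr[1]) * f,
                    ctr[2] + (v[, 2] - ctr[2]) * f),
              z_range = roi$z_range, label = roi$label)
}

#' Slice indices (1-based) covered by an ROI's z extent
#' @keywords internal
roi_z_indices <- function(roi, nz) {
  zr <- if (inherits(roi, "PolygonRoi")) roi$z_range else roi$z_index
  if (identical(zr, "all") || identical(zr, "projection")) return(seq_len(nz))
  if (length(zr) == 1L) return(as.integer(zr) + 1L)
  seq.int(as.integer(zr[1]) + 1L, as.integer(zr[2]) + 1L)
}

#' Read ROIs from a structured-text (YAML) file
#'
#' The file holds a list of records, each with a `type` (`polygon` or
#' `circle`), a `label`, and either `vertices` (list of `[x, y]` pairs) plus
#' optional `z_range`, or `center`/`diameter_px` plus optional `z_index`.
#' An empty file yields an empty list.
#'
#' @param path path to the ROI file.
#' @return list of `PolygonRoi` / `CircleRoi` objects.
#' @export
read_rois <- function(path) {
  recs <- yaml::read_yaml(path)
  if (is.null(recs)) return(list())
  lapply(recs, function(r) {
    switch(r$type,
      polygon = polygon_roi(
        vertices = do.call(rbind, lapply(r$vertices, as.numeric)),
        z_range = if (is.null(r$z_range)) "all" else
          if (identical(r$z_range, "all")) "all" else as.numeric(r$z_range),
        label = if (is.null(r$label)) "" else r$label
      ),
      circle = circle_roi(
        center = as.numeric(r$center),
        diameter_px = r$diameter_px,
        z_index = if (is.null(r$z_index)) "projection" else r$z_index,
        label = if (is.null(r$label)) "" else r$label
      ),
      stop("unknown ROI type: ", r$type)
    )
  })
}

#' Write ROIs to the structured-text (YAML) ROI format
#' @param rois list of `PolygonRoi` / `CircleRoi`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  recs <- lapply(rois, function(r) {
    if (inherits(r, "PolygonRoi")) {
      list(type = "polygon", label = r$label,
           z_range = if (identical(r$z_range, "all")) "all" else as.numeric(r$z_range),
           vertices = lapply(seq_len(nrow(r$vertices)),
                             function(i) as.numeric(r$vertices[i, ])))
    } else {
      list(type = "circle", label = r$label,
           center = as.numeric(r$center),
           diameter_px = r$diameter_px,
           z_index = r$z_index)
    }
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}
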