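#' Undecimated a-trous wavelet decomposition of a 2D plane
#'
#' Separable smoothing with the B3-spline kernel `(1,4,6,4,1)/16`, the
#' kernel holes (tap spacing) doubling at each scale, mirror boundary
#' handling. Detail plane j is `smooth_{j-1} - smooth_j`, so the input is
#' exactly the sum of all detail planes plus the final smooth plane
#' (telescoping identity).
#'
#' @param plane 2D numeric matrix, all finite.
#' @param n_scales number of detail scales (>= 1).
#' @return list with `details` (list of `n_scales` matrices) and `smooth`
#'   (the residual low-pass plane).
#' @export
atrous_decompose <- function(plane, n_scales) {
  if (!is.matrix(plane)) stop("plane must be a 2D matrix")
  if (any(!is.finite(plane))) stop("plane contains non-finite values")
  if (n_scales < 1L) stop("n_scales must be >= 1")
  w <- c(1, 4, 6, 4, 1) / 16
  offs <- -2:2
  smooth <- plane
  details <- vector("list", n_scales)
  for (j in seq_len(n_scales)) {
    h <- 2^(j - 1L)  # hole spacing
    s1 <- .conv_sep(smooth, w, offs * h, along = "rows")
    s2 <- .conv_sep(s1, w, offs * h, along = "cols")
    details[[j]] <- smooth - s2
    smooth <- s2
  }
  list(details = details, smooth = smooth)
}

# separable 5-tap convolution with arbitrary integer offsets and mirror
# (reflect-without-repeat) boundary, vectorized over whole matrices
.conv_sep <- function(m, w, offs, along) {
  n <- if (along == "rows") nrow(m) else ncol(m)
  out <- 0
  for (k in seq_along(w)) {
    idx <- seq_len(n) + offs[k]
    idx <- .mirror_index(idx, n)
    out <- out + w[k] * (if (along == "rows") m[idx, , drop = FALSE]
                         else m[, idx, drop = FALSE])
  }
  out
}

# reflect indices into 1..n without repeating the border sample
# (…3 2 | 1 2 3 … n | n-1 n-2…); for offsets beyond 2(n-1) fold repeatedly
.mirror_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  idx <- (idx - 1L) %% period
  idx <- ifelse(idx < 0, idx + period, idx)
  ifelse(idx >= n, period - idx, idx) + 1L
}

# white-noise sd fraction carried by each detail scale of the 2D B3
# a-trous transform; computed exactly from the impulse response (the
# detail filters' l2 norms), cached per n_scales
.atrous_noise_env <- new.env(parent = emptyenv())
.atrous_noise_fractions <- function(n_scales) {
  key <- as.character(n_scales)
  if (!is.null(.atrous_noise_env[[key]])) return(.atrous_noise_env[[key]])
  n <- 2^(n_scales + 2) * 4 + 1
  imp <- matrix(0, n, n)
  imp[(n + 1) %/% 2, (n + 1) %/% 2] <- 1
  dd <- atrous_decompose(imp, n_scales)$details
  fr <- vapply(dd, function(d) sqrt(sum(d^2)), 0)
  .atrous_noise_env[[key]] <- fr
  fr
}

#' Threshold wavelet detail planes by per-scale sensitivity
#'
#' For each enabled scale j the detection threshold is
#' `tau_j = (100 / sensitivity_j) * 3 * MAD(detail_j) / 0.6745`, a robust
#' noise estimate scaled so that sensitivity 100 is a 3-sigma-equivalent
#' cut; raising the sensitivity lowers the threshold and keeps more pixels.
#'
#' @param details list of detail planes from [atrous_decompose()].
#' @param settings a `WaveletSettings` object.
#' @return named list of logical masks, one per enabled scale.
#' @export
threshold_details <- function(details, settings) {
  stopifnot(inherits(settings, "WaveletSettings"))
  masks <- list()
  for (j in settings$enabled_scales) {
    if (j > length(details)) stop("scale ", j, " not present in decomposition")
    s <- settings$sensitivity_per_scale[[as.character(j)]]
    d <- details[[j]]
    sigma <- stats::mad(d)  # MAD/0.6745 (R's default constant 1.4826)
    tau <- (100 / s) * 3 * sigma
    masks[[as.character(j)]] <- d > tau
  }
  masks
}
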