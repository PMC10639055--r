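# shared fixtures and oracles, all built in code at test time

noise_off <- function() noise_model(read_noise_sd = 0, gain = 1, poisson = FALSE)

# greedy nearest-centroid matching of detections to ground truth
match_foci <- function(spots, truth, radius = 3) {
  tp <- 0L
  used <- rep(FALSE, nrow(spots))
  for (i in seq_len(nrow(truth))) {
    if (!nrow(spots)) break
    d <- sqrt((spots$x - truth$x[i])^2 + (spots$y - truth$y[i])^2 +
                (spots$z - truth$z[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= radius) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  list(tp = tp, fp = nrow(spots) - tp, fn = nrow(truth) - tp)
}

# independent winding-number point-in-polygon oracle
winding_inside <- function(px, py, v) {
  n <- nrow(v)
  vapply(seq_along(px), function(k) {
    wn <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[j, 1]; y2 <- v[j, 2]
      if (y1 <= py[k]) {
        if (y2 > py[k] &&
            (x2 - x1) * (py[k] - y1) - (px[k] - x1) * (y2 - y1) > 0) {
          wn <- wn + 1L
        }
      } else if (y2 <= py[k] &&
                 (x2 - x1) * (py[k] - y1) - (px[k] - x1) * (y2 - y1) < 0) {
        wn <- wn - 1L
      }
    }
    wn != 0L
  }, TRUE)
}

# random star-shaped (hence simple) polygon
random_simple_polygon <- function(n = 8, cx = 50, cy = 50, rmin = 10, rmax = 40) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, rmin, rmax)
  polygon_roi(cbind(cx + r * cos(th), cy + r * sin(th)))
}

# exhaustive permutation oracle for the two-sided Mann-Whitney p-value
mw_enumeration_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ranks <- seq_len(n1 + n2)
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# a small noisy stack with one hot pixel (an isolated camera spike)
hot_pixel_stack <- function(seed = 7, amplitude = 80) {
  set.seed(seed)
  arr <- array(round(pmax(rnorm(5 * 33 * 33, 100, 10), 0)), dim = c(5, 33, 33))
  arr[3, 17, 17] <- arr[3, 17, 17] + amplitude
  image_stack(arr, axes = c("z", "y", "x"))
}
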