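test_that("a-trous decomposition satisfies its exact identities", {
  # constant plane: every detail plane is exactly zero
  dec <- atrous_decompose(matrix(7, 20, 20), 3)
  for (d in dec$details) expect_true(all(d == 0))
  expect_true(all(dec$smooth == 7))

  # telescoping reconstruction on random planes
  set.seed(1)
  for (rep in 1:5) {
    m <- matrix(runif(40 * 40, 0, 1000), 40, 40)
    dec <- atrous_decompose(m, 4)
    rec <- Reduce(`+`, dec$details) + dec$smooth
    expect_lt(max(abs(rec - m)) / max(abs(m)), 1e-9)
  }

  expect_error(atrous_decompose(matrix(c(1, NA, 3, 4), 2, 2), 2), "finite")
})

test_that("impulse details equal differences of successively holed B3 kernels", {
  # direct-convolution oracle: smooth_j of a centered impulse is the
  # separable product of the j-times-holed cumulative kernels
  n <- 97
  imp <- matrix(0, n, n)
  ctr <- 49
  imp[ctr, ctr] <- 1
  dec <- atrous_decompose(imp, 3)
  w <- c(1, 4, 6, 4, 1) / 16
  kern1d <- function(h) {
    k <- rep(0, n)
    k[ctr + (-2:2) * h] <- w
    k
  }
  conv1d <- function(sig, ker) {
    # circular-free direct convolution, valid away from borders
    out <- rep(0, n)
    for (i in 1:n) {
      acc <- 0
      for (j in 1:n) {
        idx <- i - (j - ctr)
        if (idx >= 1 && idx <= n) acc <- acc + sig[idx] * ker[j]
      }
      out[i] <- acc
    }
    out
  }
  smooth <- rep(0, n); smooth[ctr] <- 1
  prev2d <- imp
  for (j in 1:3) {
    smooth <- conv1d(smooth, kern1d(2^(j - 1)))
    expect_equal(dec$details[[j]][ctr + (-4:4), ctr + (-4:4)],
                 (prev2d - outer(smooth, smooth))[ctr + (-4:4), ctr + (-4:4)],
                 tolerance = 1e-12)
    prev2d <- outer(smooth, smooth)
  }
})

test_that("detail thresholding follows the sensitivity mapping", {
  dec0 <- list(matrix(0, 30, 30), matrix(0, 30, 30))
  s <- wavelet_settings(enabled_scales = 2, sensitivity_per_scale = c("2" = 100),
                        min_size_vox = 1)
  expect_false(any(threshold_details(dec0, s)[["2"]]))

  set.seed(2)
  plane <- matrix(rnorm(100 * 100), 100, 100)
  plane[50, 50] <- 100
  masks <- threshold_details(list(matrix(0, 100, 100), plane), s)
  expect_true(masks[["2"]][50, 50])
  # MAD of the noise bounds tau near 3 at sensitivity 100
  tau_implied <- (100 / 100) * 3 * mad(plane)
  expect_lt(tau_implied, 4)

  # sensitivity 10 -> tenfold threshold -> mask nested in the sensitive one
  s10 <- wavelet_settings(enabled_scales = 2, sensitivity_per_scale = c("2" = 10),
                          min_size_vox = 1)
  m10 <- threshold_details(list(matrix(0, 100, 100), plane), s10)[["2"]]
  expect_true(all(!m10 | masks[["2"]]))
  expect_error(wavelet_settings(sensitivity_per_scale = c("2" = -1, "3" = 10)),
               "> 0")
})

test_that("3D labelling matches a voxel-set oracle on crafted masks", {
  mask <- array(FALSE, dim = c(4, 6, 6))
  mask[1, 1, 1] <- TRUE
  mask[2, 2, 2] <- TRUE  # diagonal contact -> same 26-connected component
  mask[4, 6, 6] <- TRUE  # isolated
  lab <- label_components_3d(mask)
  expect_identical(max(lab), 2L)
  expect_equal(lab[1, 1, 1], lab[2, 2, 2])
  expect_true(lab[4, 6, 6] != lab[1, 1, 1])
  expect_identical(sum(lab > 0), 3L)
})

test_that("spot detection recovers noise-free foci exactly", {
  cfg <- scene_config(image_shape = c(z = 10L, y = 96L, x = 96L), n_foci = 5,
                      noise = noise_off(), seed = 2)
  sc <- simulate_nucleus_scene(cfg)
  spots <- detect_spots(sc$stack, nucleus = shrink_polygon(cfg$nucleus, 6))
  expect_identical(nrow(spots), 5L)
  m <- match_foci(spots, sc$truth, radius = 1)
  expect_identical(m$tp, 5L)
  expect_true(all(spots$n_voxels >= 2 & spots$n_voxels <= 50))
})

test_that("degenerate detection inputs behave", {
  blank <- image_stack(array(0, dim = c(5, 33, 33)), axes = c("z", "y", "x"))
  expect_identical(nrow(detect_spots(blank)), 0L)

  # an isolated hot pixel over realistic noise fails the minimal size of 2
  expect_identical(nrow(detect_spots(hot_pixel_stack())), 0L)
})

test_that("nuclear restriction removes outside-centroid spots", {
  cfg <- scene_config(image_shape = c(z = 8L, y = 96L, x = 96L), n_foci = 10,
                      seed = 6)
  sc <- simulate_nucleus_scene(cfg)
  inner <- shrink_polygon(cfg$nucleus, 6)
  all_spots <- detect_spots(sc$stack)
  kept <- detect_spots(sc$stack, nucleus = inner)
  expect_lte(nrow(kept), nrow(all_spots))
  # every kept centroid is inside by the independent winding oracle
  if (nrow(kept)) {
    expect_true(all(winding_inside(kept$x, kept$y, inner$vertices)))
  }
  # a z-restricted nucleus drops spots outside its slab
  slab <- polygon_roi(inner$vertices, z_range = c(0, 1))
  in_slab <- detect_spots(sc$stack, nucleus = slab)
  expect_true(all(in_slab$z <= 1))
})

test_that("detection is equivariant under integer translation", {
  cfg <- scene_config(image_shape = c(z = 8L, y = 80L, x = 80L), n_foci = 4,
                      noise = noise_off(), seed = 8)
  sc <- simulate_nucleus_scene(cfg)
  arr <- sc$stack$data
  dxy <- c(5L, 3L)  # shift in x and y
  shifted <- array(10, dim = dim(arr))  # pad with the extranuclear floor
  shifted[, (1 + dxy[2]):80, (1 + dxy[1]):80] <-
    arr[, 1:(80 - dxy[2]), 1:(80 - dxy[1])]
  a <- detect_spots(sc$stack)
  b <- detect_spots(image_stack(shifted, axes = c("z", "y", "x")))
  expect_identical(nrow(b), nrow(a))
  oa <- a[order(a$x, a$y), ]
  ob <- b[order(b$x, b$y), ]
  expect_equal(ob$x, oa$x + dxy[1], tolerance = 1e-8)
  expect_equal(ob$y, oa$y + dxy[2], tolerance = 1e-8)
  expect_equal(ob$z, oa$z, tolerance = 1e-8)
})

test_that("foci are counted per nucleus on projections", {
  # two nuclei with 4 and 7 disk foci of area 9 px each
  ny <- 120; nx <- 120
  nuc <- matrix(0, ny, nx)
  foc <- matrix(0, ny, nx)
  disk <- function(m, cy, cx, r, val) {
    for (y in seq_len(ny)) for (x in seq_len(nx)) {
      if ((y - cy)^2 + (x - cx)^2 <= r^2) m[y, x] <- val
    }
    m
  }
  nuc <- disk(nuc, 35, 35, 22, 200)
  nuc <- disk(nuc, 85, 85, 22, 200)
  set.seed(1)
  pos1 <- cbind(c(25, 45, 35, 30), c(25, 45, 45, 38))
  pos2 <- cbind(c(75, 95, 85, 78, 92, 85, 95), c(75, 95, 75, 90, 82, 95, 88))
  for (i in 1:4) foc <- disk(foc, pos1[i, 1], pos1[i, 2], 1.6, 900)
  for (i in 1:7) foc <- disk(foc, pos2[i, 1], pos2[i, 2], 1.6, 900)
  nst <- image_stack(nuc, axes = c("y", "x"))
  fst <- image_stack(foc + 50, axes = c("y", "x"))
  counts <- count_foci_per_nucleus(nst, fst, min_focus_size_px = 3)
  expect_identical(sort(counts$n_foci), c(4L, 7L))

  # foci of area exactly 3 px are excluded (strictly above the threshold)
  foc3 <- matrix(0, ny, nx)
  foc3[34:36, 35] <- 900  # 3-pixel line inside nucleus 1
  c3 <- count_foci_per_nucleus(nst, image_stack(foc3 + 50, axes = c("y", "x")),
                               min_focus_size_px = 3)
  expect_true(all(c3$n_foci == 0))

  # blank foci channel -> all zero counts
  cb <- count_foci_per_nucleus(nst, image_stack(matrix(50, ny, nx),
                                                axes = c("y", "x")))
  expect_true(all(cb$n_foci == 0))

  # no nucleus -> empty result with a warning, not an error
  expect_warning(
    empty <- count_foci_per_nucleus(image_stack(matrix(0, 20, 20),
                                                axes = c("y", "x")),
                                    image_stack(matrix(0, 20, 20),
                                                axes = c("y", "x"))),
    "no nucleus")
  expect_identical(nrow(empty), 0L)
})
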