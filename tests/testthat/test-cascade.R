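# Cascade orchestration: OR-reduction, component centring, cropping,
# probability fusion, and the full per-lesion pipeline with oracle and
# classical backends.

test_that("or_reduce_slices equals elementwise any()", {
  empty <- replicate(4, matrix(FALSE, 6, 6), simplify = FALSE)
  expect_false(any(or_reduce_slices(empty)))
  one <- empty
  one[[2]][3, 4] <- TRUE
  out <- or_reduce_slices(one)
  expect_identical(which(out), which(one[[2]]))
  for (s in 1:5) {
    set.seed(s)
    stack <- array(runif(6 * 6 * 5) < 0.3, c(6, 6, 5))
    expect_identical(or_reduce_slices(stack),
                     apply(stack, c(1, 2), any))
  }
  expect_error(or_reduce_slices(list()), "empty")
})

test_that("component_centres: centroid arithmetic and separation", {
  m <- matrix(FALSE, 8, 8)
  m[2:4, 2:4] <- TRUE
  expect_equal(component_centres(m), cbind(x = 3, y = 3))
  m2 <- matrix(FALSE, 16, 16)
  m2[2:4, 2:4] <- TRUE
  m2[10:14, 11:15] <- TRUE
  cc <- component_centres(m2)
  expect_equal(nrow(cc), 2)
  lab <- label_components(m2, 26)
  for (r in 1:2) {
    k <- lab[cc[r, 1], cc[r, 2]]
    expect_gt(k, 0)  # each centre falls inside its own component here
  }
  expect_equal(nrow(component_centres(matrix(FALSE, 4, 4))), 0)
})

test_that("crop_about clamps at faces and round-trips", {
  v <- array(seq_len(32^3), c(32, 32, 32))
  ctr <- crop_about(v, c(16, 16, 16), 8)
  expect_equal(dim(ctr$crop), c(8L, 8L, 8L))
  expect_equal(ctr$offset, c(12L, 12L, 12L))
  near <- crop_about(v, c(2, 16, 16), 32)
  expect_equal(dim(near$crop), c(32L, 32L, 32L))
  expect_equal(near$offset[1], 1L)  # flush to the face, full width
  expect_error(crop_about(v, c(16, 16, 16), 40), "exceeds")

  m <- array(FALSE, c(32, 32, 32)); m[10:12, 11:13, 12:14] <- TRUE
  cr <- crop_about(m, c(11, 12, 13), 10)
  back <- uncrop(cr$crop, cr$offset, dim(m))
  expect_identical(back, m)
})

test_that("fuse_probability_maps follows the averaging rule", {
  p1 <- array(0.4, c(4, 4, 4)); p2 <- array(0.8, c(4, 4, 4))
  expect_true(all(fuse_probability_maps(p1, p2)$voxels))   # mean 0.6
  p3 <- array(0.49, c(4, 4, 4))
  expect_false(any(fuse_probability_maps(p3, p3)$voxels))
  # fusing a map with itself equals thresholding it alone
  set.seed(2)
  p <- array(runif(64), c(4, 4, 4))
  expect_identical(fuse_probability_maps(p, p)$voxels,
                   array(p >= 0.5, c(4, 4, 4)))
  expect_error(fuse_probability_maps(p1, array(0.5, c(3, 3, 3))), "shape")
})

test_that("cascade with oracle volume backends reproduces ground truth", {
  st <- toy_study(seed = 4)
  gt <- st$gt_masks[[1]]
  oracle_vol <- function(channels) {
    off <- attr(channels, "offset")
    d <- dim(channels$T1)
    idx <- lapply(1:3, function(a) off[a]:(off[a] + d[a] - 1))
    array(as.numeric(gt$voxels[idx[[1]], idx[[2]], idx[[3]]]), d)
  }
  masks <- run_cascade(st, classical_slice_segmenter(),
                       oracle_vol, oracle_vol,
                       cascade_config(crop_sizes = c(28L, 24L, 20L)))
  expect_length(masks, 1)
  expect_identical(masks[[1]]$voxels, gt$voxels)
})

test_that("classical cascade reaches dice >= 0.8 on a high-contrast phantom", {
  st <- toy_study(seed = 8, contrast = 0.8, noise = 0.02)
  masks <- run_cascade(st, classical_slice_segmenter(),
                       classical_volume_segmenter(),
                       classical_volume_segmenter(sigma = 2),
                       cascade_config(crop_sizes = c(28L, 24L, 20L)))
  expect_gte(length(masks), 1)
  dsc <- max(vapply(masks, function(m)
    dice_coefficient(m, st$gt_masks[[1]]), numeric(1)))
  expect_gte(dsc, 0.8)
})

test_that("two disjoint lesions give two disjoint masks", {
  n <- 40L
  set.seed(6)
  ax <- seq_len(n)
  mk_sphere <- function(c0, r) {
    q <- outer(outer((ax - c0[1])^2, (ax - c0[2])^2, `+`),
               (ax - c0[3])^2, `+`)
    q <= r^2
  }
  m1 <- mk_sphere(c(11, 11, 20), 4)
  m2 <- mk_sphere(c(30, 30, 20), 4)
  bg <- radrobust:::gaussian_smooth(array(rnorm(n^3), rep(n, 3L)), 4)
  v <- 0.25 + 0.04 * bg / sd(bg)
  v[m1 | m2] <- v[m1 | m2] + 0.8
  v <- v + rnorm(n^3, sd = 0.02)
  st <- structure(list(patient_id = "T02", timepoint = "BL",
                       lesion_ids = c("a", "b"),
                       channel_T1 = v, channel_T2FLAIR = v,
                       gt_masks = list(a = binary_mask(m1, 0.5),
                                       b = binary_mask(m2, 0.5)),
                       spacing_mm = rep(0.5, 3)),
                  class = "imaging_study")
  masks <- run_cascade(st, classical_slice_segmenter(),
                       classical_volume_segmenter(),
                       classical_volume_segmenter(sigma = 2),
                       cascade_config(crop_sizes = c(40L, 20L, 16L)))
  expect_equal(length(masks), 2)
  expect_false(any(masks[[1]]$voxels & masks[[2]]$voxels))
  # each ground-truth lesion is recovered by exactly one output mask
  d1 <- vapply(masks, function(m) dice_coefficient(m, st$gt_masks$a),
               numeric(1))
  d2 <- vapply(masks, function(m) dice_coefficient(m, st$gt_masks$b),
               numeric(1))
  expect_gte(max(d1), 0.7)
  expect_gte(max(d2), 0.7)
})
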