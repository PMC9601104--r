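# Segmentation quality metrics and controlled mask degradation.

test_that("dice coefficient matches definition and identities", {
  b1 <- array(FALSE, c(8, 8, 8)); b1[3:4, 3:4, 3] <- TRUE
  b2 <- array(FALSE, c(8, 8, 8)); b2[4:5, 3:4, 3] <- TRUE
  a <- binary_mask(b1, 0.5); b <- binary_mask(b2, 0.5)
  expect_equal(dice_coefficient(a, a), 1.0)
  expect_equal(dice_coefficient(a, b), 0.5)  # overlap 2 of 4: 2*2/(4+4)
  expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
  disj <- binary_mask(array(FALSE, c(8, 8, 8)), 0.5)
  disj$voxels[7, 7, 7] <- TRUE
  expect_equal(dice_coefficient(a, disj), 0)
  expect_error(dice_coefficient(a, binary_mask(array(FALSE, c(7, 7, 7)), 0.5)),
               "different grid")
  empty <- binary_mask(array(FALSE, c(8, 8, 8)), 0.5)
  expect_error(dice_coefficient(empty, empty), "empty")
})

test_that("dice equals a brute-force set-intersection oracle on random masks", {
  for (s in 1:8) {
    set.seed(s)
    v1 <- array(runif(512) < 0.3, c(8, 8, 8))
    v2 <- array(runif(512) < 0.3, c(8, 8, 8))
    if (!any(v1) || !any(v2)) next
    ids1 <- which(v1); ids2 <- which(v2)
    oracle <- 2 * length(intersect(ids1, ids2)) /
      (length(ids1) + length(ids2))
    expect_identical(dice_coefficient(binary_mask(v1, 0.5),
                                      binary_mask(v2, 0.5)), oracle)
  }
})

test_that("hausdorff distance: identity, single-pair, direction bound, symmetry", {
  s1 <- array(FALSE, c(8, 8, 8)); s1[2, 2, 2] <- TRUE
  s2 <- array(FALSE, c(8, 8, 8)); s2[5, 2, 2] <- TRUE
  m1 <- binary_mask(s1, 0.5); m2 <- binary_mask(s2, 0.5)
  expect_equal(hausdorff_distance(m1, m1), 0)
  expect_equal(hausdorff_distance(m1, m2), 1.5)  # 3 voxels at 0.5 mm
  expect_equal(hausdorff_distance(m1, m2), hausdorff_distance(m2, m1))
  # the symmetric HD dominates either directed distance
  sph <- sphere_mask(5)
  blob <- random_blob(3, n = dim(sph$voxels)[1])
  d <- dim(sph$voxels)
  ba <- radrobust:::boundary_voxels(sph)
  bb <- radrobust:::boundary_voxels(blob)
  da <- sqrt(radrobust:::.cpp_edt_sq(as.logical(ba), as.integer(d),
                                     sph$spacing_mm))
  db <- sqrt(radrobust:::.cpp_edt_sq(as.logical(bb), as.integer(d),
                                     sph$spacing_mm))
  directed <- c(max(db[ba]), max(da[bb]))
  expect_equal(hausdorff_distance(sph, blob), max(directed))
  expect_gte(hausdorff_distance(sph, blob), directed[1])
  expect_gte(hausdorff_distance(sph, blob), directed[2])
})

test_that("volume estimation error arithmetic and scale covariance", {
  va <- array(FALSE, c(10, 10, 10)); va[1:4, 1:4, 1:5] <- TRUE  # 80 voxels
  vb <- array(FALSE, c(10, 10, 10)); vb[1:4, 1:5, 1:5] <- TRUE  # 100 voxels
  a <- binary_mask(va, 0.5); b <- binary_mask(vb, 0.5)
  expect_equal(volume_estimation_error(a, a), list(cc = 0, pct = 0))
  v <- volume_estimation_error(a, b)
  expect_equal(v$cc, 20 * 0.125 / 1000)  # 0.125 mm^3 per voxel
  expect_equal(v$pct, 20)
  a2 <- binary_mask(va, 1.0); b2 <- binary_mask(vb, 1.0)
  v2 <- volume_estimation_error(a2, b2)
  expect_equal(v2$cc, 8 * v$cc)
  expect_equal(v2$pct, v$pct)
  expect_error(volume_estimation_error(a, binary_mask(array(FALSE, c(10, 10, 10)), 0.5)),
               "empty")
})

test_that("segmentation_quality consistency for identical masks", {
  sph <- sphere_mask(4)
  q <- segmentation_quality(sph, sph)
  expect_equal(q$dsc, 1)
  expect_equal(q$hd_mm, 0)
  expect_equal(q$vee_cc, 0)
})

test_that("perturb_to_target_dice returns input unchanged at target 1", {
  sph <- sphere_mask(5)
  out <- perturb_to_target_dice(sph, 1.0, seed = 3)
  expect_identical(out$voxels, sph$voxels)
  expect_equal(attr(out, "achieved_dsc"), 1)
})

test_that("perturbation hits dice targets within tolerance, all modes", {
  sph <- sphere_mask(8)
  blob <- random_blob(11)
  for (mode in c("deformation", "boundary_noise", "morphological")) {
    for (s in 1:4) {
      for (mask in list(sph, blob)) {
        out <- perturb_to_target_dice(mask, 0.85, mode = mode, seed = s)
        achieved <- dice_coefficient(out, mask)
        expect_lte(abs(achieved - 0.85), 0.01)
        expect_equal(achieved, attr(out, "achieved_dsc"))
        # single 6-connected component, non-empty
        lab <- label_components(out$voxels, 6)
        expect_equal(max(lab), 1)
      }
    }
  }
})

test_that("perturbation amplitude is monotone in achieved dice", {
  sph <- sphere_mask(7)
  d <- dim(sph$voxels)
  for (mode in c("deformation", "morphological", "boundary_noise")) {
    # rebuild the same noise context the bisection uses
    win <- radrobust:::crop_window(sph$voxels, 10L, d)
    vox <- radrobust:::crop_array(sph$voxels, win)
    bd <- dim(vox)
    ctx <- radrobust:::with_seed(5, {
      field <- radrobust:::gaussian_smooth(array(rnorm(prod(bd)), bd), 2)
      field <- field / sd(field) + rnorm(1, 0, 0.7)
      sdist <- radrobust:::signed_distance(vox)
      inner <- radrobust:::.cpp_boundary_mask(as.logical(vox),
                                              as.integer(bd))
      dim(inner) <- bd
      list(vox = vox, sd = sdist, layer = inner | (!vox & sdist > -1.6),
           noise_u = array(runif(prod(bd)), bd),
           noise_sign = sample(c(-1, 1), 1),
           noise_jit = array(runif(prod(bd), -0.5, 0.5), bd),
           noise_field = field)
    })
    amps <- seq(0.05, if (mode == "boundary_noise") 0.95 else 1.5,
                length.out = 8)
    dsc <- vapply(amps, function(a) {
      v <- radrobust:::perturb_amplitude(ctx, a, mode)
      2 * sum(v & vox) / (sum(v) + sum(vox))
    }, numeric(1))
    expect_true(all(diff(dsc) <= 1e-12),
                info = sprintf("mode %s: %s", mode,
                               paste(round(dsc, 3), collapse = " ")))
  }
})

test_that("boundary_noise perturbation preserves the centroid", {
  sph <- sphere_mask(8)
  c0 <- colMeans(which(sph$voxels, arr.ind = TRUE))
  for (s in 1:5) {
    out <- perturb_to_target_dice(sph, 0.85, mode = "boundary_noise",
                                  seed = s)
    c1 <- colMeans(which(out$voxels, arr.ind = TRUE))
    expect_lt(max(abs(c1 - c0)), 2)
  }
})

test_that("unreachable target raises with the achieved value", {
  tiny <- binary_mask(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3)), 0.5)
  # a single voxel can only jump between dice 1, 0.25 and 0 under
  # erosion/dilation, so 0.8 is unreachable at tol 0.01
  expect_error(perturb_to_target_dice(tiny, 0.8, mode = "morphological",
                                      seed = 1),
               "could not reach")
})
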