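# Resampling, normalization, margin construction, discretization and the
# stationary wavelet decomposition.

test_that("resample_isotropic: identity, constants, analytic ramp", {
  v <- array(rnorm(6 * 7 * 8), c(6, 7, 8))
  out <- resample_isotropic(v, 0.5, 0.5)
  expect_identical(out$volume, v)

  cv <- array(3.5, c(6, 6, 6))
  out <- resample_isotropic(cv, 1, 0.5)
  expect_true(all(abs(out$volume - 3.5) < 1e-12))
  expect_equal(dim(out$volume), c(12L, 12L, 12L))

  # linear ramp along x: trilinear interpolation is exact
  n <- 9
  ramp <- array(rep(seq_len(n), times = n * n), c(n, n, n))
  out <- resample_isotropic(ramp, 1, 0.5)
  i <- seq_len(dim(out$volume)[1])
  expected <- pmin(1 + (i - 1) * 0.5, n)   # clamped at the far face
  expect_lt(max(abs(out$volume[, 3, 3] - expected)), 1e-9)

  expect_error(resample_isotropic(v, -1, 0.5), "positive")
})

test_that("nearest-neighbour resampling keeps masks binary", {
  m <- array(0, c(8, 8, 8)); m[3:5, 3:5, 3:5] <- 1
  out <- resample_isotropic(m, 1, 0.4, method = "nearest")
  expect_true(all(out$volume %in% c(0, 1)))
})

test_that("normalize_unit maps to [0,1], records coefficients, idempotent", {
  v <- array(c(10, 20, 30, 25), c(2, 2, 1))
  out <- normalize_unit(v)
  expect_equal(out$min, 10)
  expect_equal(out$max, 30)
  expect_equal(out$volume[1, 2, 1], 30 / 20 - 0.5)  # value 30 -> 1
  expect_equal(range(out$volume), c(0, 1))
  expect_equal(out$volume[2, 1, 1], 0.5)            # value 20 -> 0.5
  expect_identical(normalize_unit(out$volume)$volume, out$volume)
  expect_error(normalize_unit(array(1, c(2, 2, 2))), "constant")
})

test_that("margin equals brute-force euclidean shell for a point tumour", {
  d <- c(25L, 25L, 25L)
  vox <- array(FALSE, d); vox[13, 13, 13] <- TRUE
  tum <- binary_mask(vox, 0.5)
  rois <- margin_mask(tum, 5)
  co <- which(array(TRUE, d), arr.ind = TRUE)
  dist_mm <- sqrt(colSums((t(co) - c(13, 13, 13))^2)) * 0.5
  expect_equal(sum(rois$margin$voxels), sum(dist_mm > 0 & dist_mm <= 5))
  # exact voxel set, not only the count
  expect_identical(as.vector(rois$margin$voxels),
                   as.vector(dist_mm > 0 & dist_mm <= 5))
})

test_that("margin of width one voxel follows the euclidean metric", {
  d <- c(9L, 9L, 9L)
  vox <- array(FALSE, d); vox[5, 5, 5] <- TRUE
  rois <- margin_mask(binary_mask(vox, 0.5), 0.5)
  # exactly the 6-connected shell: face diagonals are sqrt(2)/2 mm > 0.5
  expect_equal(sum(rois$margin$voxels), 6)
})

test_that("tumour and margin are disjoint for random masks and clip at edges", {
  for (s in 1:5) {
    blob <- random_blob(s, n = 20)
    rois <- margin_mask(blob, 5)
    expect_false(any(rois$tumour$voxels & rois$margin$voxels))
    expect_equal(dim(rois$margin$voxels), dim(blob$voxels))
  }
})

test_that("discretize follows the stated binning rule", {
  v <- array(c(0, 0.5, 1.0, 0.2), c(4, 1, 1))
  roi <- array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1))
  disc <- discretize(v, roi, 2)
  expect_equal(disc$levels[1:3], c(1L, 2L, 2L))
  expect_equal(disc$levels[4], 0L)
  const <- discretize(array(2, c(3, 1, 1)), array(TRUE, c(3, 1, 1)), 8)
  expect_true(all(const$levels == 1L))
  for (s in 1:3) {
    set.seed(s)
    v <- array(rnorm(64), c(4, 4, 4))
    disc <- discretize(v, array(TRUE, c(4, 4, 4)), 7)
    expect_lte(max(disc$levels), 7L)
    expect_gte(min(disc$levels), 1L)
  }
})

test_that("wavelet decomposition: 8 same-shape sub-bands, vanishing high-pass", {
  v <- array(5, c(12, 14, 12))
  wb <- wavelet_subbands(v)
  expect_length(wb, 8)
  expect_named(wb, c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  for (nm in names(wb)) expect_equal(dim(wb[[nm]]), dim(v))
  # any band with a high-pass axis annihilates constants
  for (nm in setdiff(names(wb), "LLL"))
    expect_lt(max(abs(wb[[nm]])), 1e-10)
  # LLL gain for constants is sqrt(2) per axis
  expect_equal(wb$LLL[3, 3, 3], 5 * 2^(3 / 2), tolerance = 1e-10)
  expect_error(wavelet_subbands(array(1, c(4, 4, 4))), "too small")
})

test_that("low-pass contracts the energy of white noise", {
  for (s in 1:10) {
    set.seed(s)
    v <- array(rnorm(16^3), c(16, 16, 16))
    wb <- wavelet_subbands(v)
    # white noise is mostly annihilated by the low-pass cascade: the LLL
    # energy stays near the input energy, far below the 8x coherent gain
    expect_lt(sum(wb$LLL^2), sum(v^2) * 1.5)
    # band energies sum to the input energy times the redundancy factor
    tot <- Reduce(`+`, lapply(wb, function(b) sum(b^2)))
    expect_equal(tot, sum(v^2) * 8, tolerance = 0.05)
  }
})

test_that("coif1 filters satisfy the orthogonal filter identities", {
  f <- radrobust:::coif1_filters()
  expect_equal(sum(f$lo), sqrt(2), tolerance = 1e-9)
  expect_equal(sum(f$lo^2), 1, tolerance = 1e-9)
  expect_equal(sum(f$hi), 0, tolerance = 1e-12)
  expect_equal(sum(f$lo * f$hi), 0, tolerance = 1e-12)
})
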