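# Feature families: first-order, shape, and the five texture-matrix
# families, each checked against hand computations or brute-force
# enumeration oracles.

test_that("first-order features: hand computations and degenerate ROI", {
  v <- array(c(1, 2, 3, 4), c(4, 1, 1))
  roi <- array(TRUE, c(4, 1, 1))
  fo <- first_order_features(v, roi, spacing_mm = c(1, 1, 1))
  expect_length(fo, 19)
  expect_equal(fo[["Mean"]], 2.5)
  expect_equal(fo[["Variance"]], 1.25)   # population variance
  expect_equal(fo[["Range"]], 3)
  expect_equal(fo[["Energy"]], 30)
  expect_equal(fo[["Median"]], 2.5)
  expect_equal(fo[["RootMeanSquared"]], sqrt(30 / 4))

  cv <- array(2.5, c(3, 3, 1))
  fo <- first_order_features(cv, array(TRUE, c(3, 3, 1)))
  expect_equal(fo[["Mean"]], 2.5)
  expect_equal(fo[["Minimum"]], 2.5)
  expect_equal(fo[["Maximum"]], 2.5)
  expect_equal(fo[["Median"]], 2.5)
  expect_equal(fo[["Variance"]], 0)
  expect_equal(fo[["Range"]], 0)
  expect_equal(fo[["Uniformity"]], 1)
  expect_error(first_order_features(cv, array(FALSE, c(3, 3, 1))), "empty")
})

test_that("first-order percentiles agree with type-7 quantiles", {
  set.seed(9)
  x <- rnorm(500)
  v <- array(x, c(500, 1, 1))
  fo <- first_order_features(v, array(TRUE, c(500, 1, 1)))
  q <- quantile(x, c(0.1, 0.9), type = 7, names = FALSE)
  expect_equal(fo[["10Percentile"]], q[1])
  expect_equal(fo[["90Percentile"]], q[2])
  expect_equal(fo[["InterquartileRange"]],
               diff(quantile(x, c(0.25, 0.75), type = 7, names = FALSE)))
})

test_that("shape features: count, digital ball accuracy, symmetry", {
  sph <- sphere_mask(10, spacing = 1, pad = 3)
  sf <- shape_features(sph)
  expect_length(sf, 26)
  expect_gte(sf[["Sphericity"]], 0.95)
  expect_lte(sf[["Sphericity"]], 1.0)
  expect_gte(sf[["Flatness"]], 0.95)   # symmetry forces all axes equal
  expect_lte(sf[["Flatness"]], 1.0)
  expect_equal(sf[["Maximum3DDiameter"]], 20)
  expect_equal(sf[["Elongation"]], 1, tolerance = 1e-9)
  # mesh volume and surface within a few percent of the analytic ball
  expect_equal(sf[["MeshVolume"]], 4 / 3 * pi * 1000, tolerance = 0.05)
  expect_equal(sf[["SurfaceArea"]], 4 * pi * 100, tolerance = 0.05)
  expect_equal(sf[["VoxelVolume"]], sum(sph$voxels))
  expect_error(shape_features(binary_mask(array(FALSE, c(3, 3, 3)), 1)),
               "empty")
})

test_that("shape features scale correctly with voxel spacing", {
  blob <- random_blob(5, n = 18)
  sf1 <- shape_features(blob)
  sf2 <- shape_features(binary_mask(blob$voxels, blob$spacing_mm * 2))
  expect_equal(sf2[["MeshVolume"]], 8 * sf1[["MeshVolume"]],
               tolerance = 1e-9)
  expect_equal(sf2[["SurfaceArea"]], 4 * sf1[["SurfaceArea"]],
               tolerance = 1e-9)
  expect_equal(sf2[["Maximum3DDiameter"]], 2 * sf1[["Maximum3DDiameter"]])
  expect_equal(sf2[["Sphericity"]], sf1[["Sphericity"]], tolerance = 1e-9)
  expect_equal(sf2[["Elongation"]], sf1[["Elongation"]], tolerance = 1e-9)
})

test_that("texture matrices equal brute-force enumeration on random ROIs", {
  for (s in 1:6) {
    disc <- random_levels(s, dims = c(sample(3:5, 1), sample(3:5, 1),
                                      sample(3:5, 1)))
    if (!any(disc$levels > 0)) next
    lev <- as.integer(disc$levels)
    dm <- as.integer(dim(disc$levels))
    ng <- disc$n_bins

    got <- radrobust:::.cpp_glcm(lev, dm, ng)
    dim(got) <- c(ng, ng, 13)
    want <- oracle_glcm_counts(disc)
    # direction sets may be ordered differently: compare sorted slices and
    # the direction-summed matrix
    expect_equal(apply(got, c(1, 2), sum), apply(want, c(1, 2), sum))
    expect_equal(sort(apply(got, 3, paste, collapse = ",")),
                 sort(apply(want, 3, paste, collapse = ",")))

    runs <- radrobust:::.cpp_glrlm(lev, dm, ng)
    dim(runs) <- c(ng, length(runs) / (13 * ng), 13)
    wruns <- oracle_glrlm_counts(disc)
    mr <- max(dim(runs)[2], dim(wruns)[2])
    pad <- function(a) {
      out <- array(0, c(ng, mr, 13)); out[, seq_len(dim(a)[2]), ] <- a; out
    }
    got_r <- pad(runs); want_r <- pad(wruns)
    expect_equal(apply(got_r, c(1, 2), sum), apply(want_r, c(1, 2), sum))
    expect_equal(sort(apply(got_r, 3, paste, collapse = ",")),
                 sort(apply(want_r, 3, paste, collapse = ",")))

    zones <- radrobust:::.cpp_glszm(lev, dm, ng)
    wzones <- oracle_glszm_zones(disc)
    key <- function(z) sort(paste(z[, 1], z[, 2]))
    expect_equal(key(zones), key(wzones))

    gldm <- radrobust:::.cpp_gldm(lev, dm, ng, 0L)
    dim(gldm) <- c(ng, 27)
    expect_equal(unname(gldm), oracle_gldm(disc, 0))

    ngt <- radrobust:::.cpp_ngtdm(lev, dm, ng)
    expect_equal(unname(ngt), oracle_ngtdm(disc), tolerance = 1e-12)
  }
})

test_that("fused texture pass equals the standalone builders", {
  disc <- random_levels(17, dims = c(6, 5, 4), n_bins = 5)
  lev <- as.integer(disc$levels)
  dm <- as.integer(dim(disc$levels))
  tm <- radrobust:::texture_matrices(disc, alpha = 0)
  expect_equal(as.vector(tm$glcm),
               as.vector(radrobust:::.cpp_glcm(lev, dm, 5L)))
  expect_equal(as.vector(tm$glrlm),
               as.vector(radrobust:::.cpp_glrlm(lev, dm, 5L)))
  expect_equal(as.vector(tm$gldm),
               as.vector(radrobust:::.cpp_gldm(lev, dm, 5L, 0L)))
  expect_equal(as.vector(tm$ngtdm),
               as.vector(radrobust:::.cpp_ngtdm(lev, dm, 5L)))
  key <- function(z) sort(paste(z[, 1], z[, 2]))
  expect_equal(key(tm$glszm),
               key(radrobust:::.cpp_glszm(lev, dm, 5L)))
})

test_that("GLCM features: degenerate and hand-enumerated cases", {
  const <- list(levels = array(1L, c(3, 3, 1)), n_bins = 4L)
  g <- glcm_features(const)
  expect_length(g, 24)
  expect_equal(g[["JointEnergy"]], 1)
  expect_equal(g[["Contrast"]], 0)
  expect_equal(g[["MaximumProbability"]], 1)

  # 2x2x1 checkerboard: x and y neighbours always differ, diagonals match
  lev <- array(0L, c(2, 2, 1))
  lev[1, 1, 1] <- 1L; lev[2, 2, 1] <- 1L; lev[2, 1, 1] <- 2L; lev[1, 2, 1] <- 2L
  disc <- list(levels = lev, n_bins = 2L)
  # directions present: x (2 pairs |d|=1), y (2 pairs |d|=1),
  # diag (1 pair d=0), antidiag (1 pair d=0) -> mean contrast = 0.5
  expect_equal(glcm_features(disc)[["Contrast"]], 0.5)
  # matrix normalization: averaged matrix sums to one
  counts <- radrobust:::.cpp_glcm(as.integer(lev), c(2L, 2L, 1L), 2L)
  dim(counts) <- c(2, 2, 13)
  used <- apply(counts, 3, sum) > 0
  P <- Reduce(`+`, lapply(which(used), function(k)
    counts[, , k] / sum(counts[, , k]))) / sum(used)
  expect_equal(sum(P), 1)
})

test_that("run/zone/dependence features on a constant ROI", {
  const <- list(levels = array(1L, c(3, 3, 1)), n_bins = 3L)
  rl <- glrlm_features(const)
  expect_length(rl, 16)
  # runs per direction on a 3x3 plane: 3 lines along x or y, 5 diagonal
  # lines, and 9 singleton runs in any out-of-plane direction;
  # RunPercentage averages (#runs / #voxels) over the 13 directions
  runs_per_dir <- c(3, 3, 5, 5, rep(9, 9))
  expect_equal(rl[["RunPercentage"]], mean(runs_per_dir / 9))
  expect_equal(rl[["GrayLevelNonUniformityNormalized"]], 1)

  sz <- glszm_features(const)
  expect_length(sz, 16)
  expect_equal(sz[["ZonePercentage"]], 1 / 9)  # exactly one zone
  expect_equal(sz[["LargeAreaEmphasis"]], 81)

  ng <- ngtdm_features(const)
  expect_length(ng, 5)
  expect_equal(ng[["Contrast"]], 0)
  expect_equal(ng[["Busyness"]], 0)

  gd <- gldm_features(const)
  expect_length(gd, 14)
  expect_equal(gd[["HighGrayLevelEmphasis"]], 1)
  # centre voxel has 8 dependent neighbours (size 9), edges 5 (size 6),
  # corners 3 (size 4)
  expect_equal(gd[["LargeDependenceEmphasis"]],
               (1 * 81 + 4 * 36 + 4 * 16) / 9)
})

test_that("direction-averaged GLCM/GLRLM features are rotation invariant", {
  disc <- random_levels(23, dims = c(6, 6, 6), n_bins = 5)
  rot <- list(levels = aperm(disc$levels[, rev(seq_len(6)), ],
                             c(2, 1, 3)),
              n_bins = disc$n_bins)  # 90 degree rotation about z
  expect_equal(glcm_features(disc), glcm_features(rot))
  expect_equal(glrlm_features(disc), glrlm_features(rot))
})
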