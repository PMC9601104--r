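#' Morphological (shape) features of a binary mask
#'
#' 17 three-dimensional descriptors plus 9 two-dimensional descriptors of
#' the largest-area axial slice, 26 in total. Surfaces are measured on an
#' iso-surface mesh (marching tetrahedra in 3D, marching squares in 2D) of
#' the lightly smoothed mask indicator, which removes the voxelization
#' bias of face counting; axis lengths come from the eigenvalues of the
#' physical-coordinate covariance (axis length `4 * sqrt(lambda)`).
#'
#' @param mask non-empty [binary_mask()].
#' @return named numeric vector of length 26.
#' @export
shape_features <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  vox <- mask$voxels
  if (!any(vox)) stop("mask is empty")
  sp <- mask$spacing_mm
  # every descriptor is translation invariant: work on the tight bounding
  # box (one-voxel pad) to keep mesh and distance passes small
  win <- crop_window(vox, 1L, dim(vox))
  vox <- crop_array(vox, win)
  d <- dim(vox)

  mesh <- mask_mesh_area_volume(vox, sp)
  A <- mesh$area
  V <- mesh$volume
  voxvol <- sum(vox) * prod(sp)
  R_eq <- (3 * V / (4 * pi))^(1 / 3)
  sphericity <- pi^(1 / 3) * (6 * V)^(2 / 3) / A

  # principal axes from the physical voxel-coordinate covariance
  co <- voxel_coords(vox)
  pc <- sweep(co, 2, c(1, 1, 1)) %*% diag(sp)
  n <- nrow(pc)
  if (n > 1) {
    cv <- crossprod(sweep(pc, 2, colMeans(pc))) / n
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  # maximum diameters from boundary voxel centres (physical coordinates).
  # The extreme pairs of any set lie on its convex hull, so the boundary
  # of the filled support suffices (exact for solid masks; for shell ROIs
  # it ignores the interior cavity, which cannot carry an extreme point).
  filled <- fill_holes(vox)
  bnd <- .cpp_boundary_mask(as.logical(filled), as.integer(d))
  dim(bnd) <- d
  dia <- .cpp_max_diameters(voxel_coords(bnd), sp)
  max3d <- dia$max3d
  max2d_slice <- dia$slice    # in-plane (x, y), per z slice
  max2d_column <- dia$column  # (x, z), per y column
  max2d_row <- dia$row        # (y, z), per x row

  # 2D block: largest-area axial slice
  slice_areas <- apply(vox, 3, sum)
  zi <- which.max(slice_areas)
  sl <- vox[, , zi, drop = TRUE]
  twod <- slice_shape_features(sl, sp[1:2])

  c(MeshVolume = V,
    VoxelVolume = voxvol,
    SurfaceArea = A,
    SurfaceVolumeRatio = A / V,
    Sphericity = sphericity,
    Compactness1 = V / (sqrt(pi) * A^1.5),
    Compactness2 = 36 * pi * V^2 / A^3,
    SphericalDisproportion = A / (4 * pi * R_eq^2),
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = max2d_slice,
    Maximum2DDiameterColumn = max2d_column,
    Maximum2DDiameterRow = max2d_row,
    MajorAxisLength = axes[1],
    MinorAxisLength = axes[2],
    LeastAxisLength = axes[3],
    Elongation = elong,
    Flatness = flat,
    twod)
}

# complement components not touching the grid border are interior cavities
fill_holes <- function(vox) {
  lab <- label_components(!vox, connectivity = 6)
  d <- dim(vox)
  border_labs <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                          lab[, , c(1, d[3])]))
  vox | (lab > 0 & !(lab %in% border_labs))
}

# iso-surface area and volume of a binary mask via marching tetrahedra on
# the smoothed indicator (sigma in voxel units); falls back to the raw
# indicator when smoothing would sink the object below the iso level
mask_mesh_area_volume <- function(vox, sp, sigma = 0.8) {
  d <- dim(vox)
  f <- gaussian_smooth(array(as.numeric(vox), d), sigma)
  if (max(f) < 0.55) f <- array(as.numeric(vox), d)
  .cpp_mesh_area_volume(as.numeric(f), as.integer(d), as.numeric(sp), 0.5)
}

slice_shape_features <- function(sl, sp2, sigma = 0.8) {
  d2 <- dim(sl)
  f <- gaussian_smooth(array(as.numeric(sl), c(d2, 1L)), sigma)
  f <- array(f, d2)
  if (max(f) < 0.55) f <- array(as.numeric(sl), d2)
  ct <- .cpp_contour_perimeter_area(as.numeric(f), as.integer(d2),
                                    as.numeric(sp2), 0.5)
  A2 <- ct$area
  P2 <- ct$perimeter
  co <- which(sl, arr.ind = TRUE)
  pc <- sweep(co, 2, c(1, 1)) %*% diag(sp2)
  n <- nrow(pc)
  if (n > 1) {
    cv <- crossprod(sweep(pc, 2, colMeans(pc))) / n
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0)
  # boundary pixels of the slice (treat as one-slice 3D mask)
  b3 <- .cpp_boundary_mask(as.logical(array(sl, c(d2, 1L))),
                           as.integer(c(d2, 1L)))
  dim(b3) <- c(d2, 1L)
  bc <- which(b3[, , 1, drop = FALSE], arr.ind = TRUE)[, 1:2, drop = FALSE]
  bc <- sweep(bc, 2, c(1, 1)) %*% diag(sp2)
  maxd <- if (nrow(bc) >= 2) .cpp_max_pair_dist(bc) else 0
  c(MeshSurface2D = A2,
    PixelSurface2D = n * prod(sp2),
    Perimeter2D = P2,
    PerimeterSurfaceRatio2D = P2 / A2,
    Sphericity2D = 2 * sqrt(pi * A2) / P2,
    MaximumDiameter2D = maxd,
    MajorAxisLength2D = 4 * sqrt(ev[1]),
    MinorAxisLength2D = 4 * sqrt(ev[2]),
    Elongation2D = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1)
}
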