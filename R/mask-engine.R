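#' Dice similarity coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`; symmetric, 1 for identical masks.
#'
#' @param a,b [binary_mask()] objects on the same grid, both non-empty.
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  check_same_grid(a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na == 0 && nb == 0) stop("dice undefined for two empty masks")
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Hausdorff distance between mask surfaces, in mm
#'
#' Maximum symmetric surface distance between boundary voxel centres; a
#' voxel is boundary if any of its 6-neighbours (or the grid edge) is
#' background. Computed via a Euclidean distance transform of each
#' boundary set.
#'
#' @inheritParams dice_coefficient
#' @param percentile optional percentile of the symmetric surface-distance
#'   distribution in place of the maximum (e.g. 95); `NULL` (default)
#'   gives the classical maximum Hausdorff distance.
#' @return distance in mm.
#' @export
hausdorff_distance <- function(a, b, percentile = NULL) {
  check_same_grid(a, b)
  if (!any(a$voxels) || !any(b$voxels)) stop("masks must be non-empty")
  d <- dim(a$voxels)
  ba <- boundary_voxels(a); bb <- boundary_voxels(b)
  da <- sqrt(.cpp_edt_sq(as.logical(ba), as.integer(d), a$spacing_mm))
  db <- sqrt(.cpp_edt_sq(as.logical(bb), as.integer(d), a$spacing_mm))
  d_ab <- db[ba]   # from each boundary voxel of a to b's boundary
  d_ba <- da[bb]
  if (is.null(percentile)) max(d_ab, d_ba)
  else max(quantile(d_ab, percentile / 100), quantile(d_ba, percentile / 100))
}

#' Volume estimation error in cc and percent
#'
#' `|vol(a) - vol(b)|` with volume = foreground count times voxel volume
#' (cm^3), and the same as a percentage of the ground-truth volume.
#'
#' @param a predicted mask.
#' @param b ground-truth mask (non-empty).
#' @return list with `cc` and `pct`.
#' @export
volume_estimation_error <- function(a, b) {
  check_same_grid(a, b)
  if (!any(b$voxels)) stop("ground-truth mask is empty")
  va <- mask_volume_cc(a); vb <- mask_volume_cc(b)
  cc <- abs(va - vb)
  list(cc = cc, pct = 100 * cc / vb)
}

#' All segmentation quality metrics for one mask pair
#'
#' @inheritParams volume_estimation_error
#' @return list with `dsc`, `hd_mm`, `vee_cc`, `vee_pct`.
#' @export
segmentation_quality <- function(a, b) {
  vee <- volume_estimation_error(a, b)
  list(dsc = dice_coefficient(a, b), hd_mm = hausdorff_distance(a, b),
       vee_cc = vee$cc, vee_pct = vee$pct)
}

# signed Euclidean distance (voxel units): positive inside the mask,
# negative outside, zero crossing at the boundary
signed_distance <- function(vox) {
  d <- dim(vox)
  dout <- sqrt(.cpp_edt_sq(as.logical(vox), as.integer(d), c(1, 1, 1)))
  din <- sqrt(.cpp_edt_sq(as.logical(!vox), as.integer(d), c(1, 1, 1)))
  ifelse(vox, din - 0.5, -(dout - 0.5))
}

# one perturbation evaluation at a given amplitude on the precomputed
# context; larger amplitude = more degraded mask
perturb_amplitude <- function(ctx, amplitude, mode) {
  if (mode == "boundary_noise") {
    # flip boundary-layer voxels (inner boundary and outer one-voxel
    # shell) independently with probability = amplitude
    flip <- ctx$layer & (ctx$noise_u < amplitude)
    xor(ctx$vox, flip)
  } else if (mode == "morphological") {
    # continuous erosion (sign < 0) or dilation (sign > 0) by `amplitude`
    # voxels via the signed distance transform; the per-voxel jitter
    # randomizes the effective structuring element so partial shells are
    # reachable and dice varies continuously with the amplitude
    ctx$sd + ctx$noise_sign * amplitude + ctx$noise_jit * pmin(amplitude, 1) >= 0
  } else {  # deformation: boundary displaced by a smooth random field
    ctx$sd + amplitude * ctx$noise_field >= 0
  }
}

#' Degrade a mask to a prescribed Dice target
#'
#' Emulates segmentation models of controlled accuracy: a perturbation
#' amplitude is bisected until the Dice coefficient between the degraded
#' mask and the input hits `target_dsc` within `tol`. Three perturbation
#' modes are available: random boundary-voxel flips (`boundary_noise`),
#' signed-distance erosion/dilation (`morphological`), and displacement of
#' the boundary by a smooth Gaussian random field (`deformation`, default:
#' the closest analogue of real segmentation-model errors). The result is
#' re-binarized and reduced to its largest 6-connected component.
#'
#' @param mask non-empty [binary_mask()].
#' @param target_dsc target Dice in `(0, 1]`.
#' @param mode perturbation mode.
#' @param seed integer seed; the perturbation is a pure function of
#'   `(mask, target_dsc, mode, seed)`.
#' @param tol acceptable `|achieved - target|` (default 0.01).
#' @param max_iter bisection iteration budget.
#' @return degraded [binary_mask()] with attribute `achieved_dsc`.
#' @export
perturb_to_target_dice <- function(mask, target_dsc,
                                   mode = c("deformation", "boundary_noise",
                                            "morphological"),
                                   seed = 1L, tol = 0.01, max_iter = 60L) {
  mode <- match.arg(mode)
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$voxels)) stop("mask is empty")
  if (target_dsc <= 0 || target_dsc > 1)
    stop("target_dsc must be in (0, 1]")
  if (target_dsc == 1) {
    attr(mask, "achieved_dsc") <- 1
    return(mask)
  }
  d <- dim(mask$voxels)
  # the perturbation only touches a neighbourhood of the mask: work on the
  # padded bounding box and place the result back at the end
  pad <- 10L
  win <- crop_window(mask$voxels, pad, d)
  vox <- crop_array(mask$voxels, win)
  bd <- dim(vox)
  sdist <- signed_distance(vox)
  inner <- .cpp_boundary_mask(as.logical(vox), as.integer(bd))
  dim(inner) <- bd
  n_gt <- sum(vox)
  gt_box <- vox
  best <- NULL
  # dice is monotone but not continuous in the amplitude (component
  # cleanup and voxel quantization produce jumps); when a jump straddles
  # the target, redraw the noise and try again
  for (attempt in seq_len(6L)) {
    ctx <- with_seed(child_seed(seed, "draw", attempt), {
      field <- gaussian_smooth(array(rnorm(prod(bd)), bd), 2)
      # unit-variance smooth field plus a random DC component:
      # segmentation models err in volume as well as contour, so the
      # displacement field carries a per-mask inflation/erosion bias
      field <- field / stats::sd(field) + rnorm(1, 0, 0.7)
      list(vox = vox, sd = sdist,
           layer = inner | (!vox & sdist > -1.6),  # plus one-voxel shell
           noise_u = array(runif(prod(bd)), bd),
           noise_sign = sample(c(-1, 1), 1),
           noise_jit = array(runif(prod(bd), -0.5, 0.5), bd),
           noise_field = field)
    })
    eval_amp <- function(a) {
      v <- perturb_amplitude(ctx, a, mode)
      if (!any(v)) return(list(dsc = 0, vox = NULL))
      v <- largest_component(v, connectivity = 6)
      list(dsc = 2 * sum(v & gt_box) / (sum(v) + n_gt), vox = v)
    }
    # bracket: dice(0) = 1, find hi with dice(hi) < target
    hi <- switch(mode, boundary_noise = 1, morphological = 2,
                 deformation = 1)
    lo <- 0
    r <- eval_amp(hi)
    grow <- 0
    while (r$dsc > target_dsc && grow < 12 && mode != "boundary_noise") {
      hi <- hi * 2
      r <- eval_amp(hi)
      grow <- grow + 1
    }
    cand <- r
    if (abs(cand$dsc - target_dsc) > tol) {
      for (it in seq_len(max_iter)) {
        mid <- (lo + hi) / 2
        r <- eval_amp(mid)
        if (abs(r$dsc - target_dsc) < abs(cand$dsc - target_dsc))
          cand <- r
        if (abs(cand$dsc - target_dsc) <= tol) break
        if (r$dsc > target_dsc) lo <- mid else hi <- mid
      }
    }
    if (is.null(best) ||
        (!is.null(cand$vox) &&
           abs(cand$dsc - target_dsc) < abs(best$dsc - target_dsc)))
      best <- cand
    if (!is.null(best$vox) && abs(best$dsc - target_dsc) <= tol) break
  }
  if (is.null(best$vox) || abs(best$dsc - target_dsc) > tol)
    stop(sprintf(
      "could not reach target dice %.3f (achieved %.3f) within budget",
      target_dsc, if (is.null(best$vox)) 0 else best$dsc))
  full <- array(FALSE, d)
  full[win[[1]], win[[2]], win[[3]]] <- best$vox
  out <- binary_mask(full, mask$spacing_mm)
  attr(out, "achieved_dsc") <- best$dsc
  out
}
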