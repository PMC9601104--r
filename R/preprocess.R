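#' Resample a volume onto an isotropic grid
#'
#' Trilinear interpolation for image volumes and nearest-neighbour for
#' masks, as conventional for radiomic preprocessing of coregistered MR.
#' The output grid has `round(dim * in_spacing / out_spacing)` voxels per
#' axis; voxel i sits at physical coordinate `i * spacing` so a spacing
#' match is the identity.
#'
#' @param volume 3D numeric array.
#' @param in_spacing,out_spacing numeric length-3 (or scalar) voxel spacing
#'   in mm; must be strictly positive.
#' @param method "trilinear" or "nearest".
#' @return list with `volume` (resampled array) and `spacing_mm`.
#' @export
resample_isotropic <- function(volume, in_spacing, out_spacing,
                               method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (length(in_spacing) == 1) in_spacing <- rep(in_spacing, 3)
  if (length(out_spacing) == 1) out_spacing <- rep(out_spacing, 3)
  if (any(in_spacing <= 0) || any(out_spacing <= 0))
    stop("voxel spacings must be strictly positive")
  d <- dim(volume)
  stopifnot(length(d) == 3)
  out_dim <- pmax(1L, as.integer(round(d * in_spacing / out_spacing)))
  if (all(out_dim == d) && isTRUE(all.equal(in_spacing, out_spacing)))
    return(list(volume = volume, spacing_mm = as.numeric(out_spacing)))
  v <- .cpp_resample(as.numeric(volume), as.integer(d),
                     as.numeric(in_spacing), as.numeric(out_spacing),
                     out_dim, method == "nearest")
  dim(v) <- out_dim
  list(volume = v, spacing_mm = as.numeric(out_spacing))
}

#' Min-max normalize voxel intensities to the unit interval
#'
#' Whole-volume normalization `(v - min) / (max - min)`, recording the
#' coefficients used.
#'
#' @param volume numeric array with at least two distinct values.
#' @return list with `volume`, `min`, `max`.
#' @export
normalize_unit <- function(volume) {
  rng <- range(volume)
  if (rng[1] == rng[2])
    stop("cannot normalize a constant volume (zero intensity range)")
  list(volume = (volume - rng[1]) / (rng[2] - rng[1]),
       min = rng[1], max = rng[2])
}

#' Build the tumour / margin ROI pair
#'
#' The margin is the shell of voxels whose Euclidean distance to the tumour
#' (computed on voxel centres with the mask's spacing) lies in
#' `(0, width_mm]`, clipped at the grid boundary. Tumour and margin are
#' disjoint by construction.
#'
#' @param tumour a [binary_mask()] with at least one foreground voxel.
#' @param width_mm margin width in mm (default 5, the peritumoural shell
#'   conventionally analysed alongside the tumour core).
#' @return list of class `roi_pair` with `tumour` and `margin` masks.
#' @export
margin_mask <- function(tumour, width_mm = 5) {
  stopifnot(inherits(tumour, "binary_mask"), width_mm > 0)
  if (!any(tumour$voxels)) stop("tumour mask is empty")
  d <- dim(tumour$voxels)
  dsq <- .cpp_edt_sq(as.logical(tumour$voxels), as.integer(d),
                     as.numeric(tumour$spacing_mm))
  margin <- !tumour$voxels & dsq <= width_mm^2 + 1e-9
  dim(margin) <- d
  if (!any(margin)) stop("margin is empty after clipping to the grid")
  structure(list(tumour = tumour,
                 margin = binary_mask(margin, tumour$spacing_mm),
                 width_mm = width_mm),
            class = "roi_pair")
}

#' Discretize ROI intensities into equal-width gray-level bins
#'
#' Bins span the ROI intensity range; `level = min(floor((v - min)/w) + 1,
#' n_bins)`. A constant ROI maps every voxel to level 1.
#'
#' @param volume numeric 3D array.
#' @param roi logical array (same shape) marking ROI voxels.
#' @param n_bins number of gray levels (>= 2).
#' @return list with `levels` (integer array, 0 outside the ROI) and
#'   `n_bins`.
#' @export
discretize <- function(volume, roi, n_bins = 32) {
  stopifnot(n_bins >= 2, identical(dim(volume), dim(roi)))
  if (!any(roi)) stop("ROI is empty")
  lev <- array(0L, dim(volume))
  lev[roi] <- discretize_codes(volume[roi], n_bins)
  list(levels = lev, n_bins = as.integer(n_bins))
}

# gray-level codes for a vector of ROI intensities
discretize_codes <- function(vals, n_bins) {
  lo <- min(vals); hi <- max(vals)
  if (hi == lo) return(rep(1L, length(vals)))
  w <- (hi - lo) / n_bins
  pmin(as.integer((vals - lo) %/% w) + 1L, as.integer(n_bins))
}

# coiflet-1 analysis filters; high-pass by the quadrature-mirror relation
coif1_filters <- function() {
  lo <- c(-0.015655728135465e0, -0.072732619512854e0, 0.384864846864203e0,
          0.852572020212255e0, 0.337897662457809e0, -0.072732619512854e0)
  n <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1)
  list(lo = lo, hi = hi)
}

#' Single-level stationary 3D wavelet decomposition
#'
#' Undecimated separable transform with periodic boundary extension; every
#' sub-band keeps the input shape so ROI masks apply unchanged. Sub-band
#' letters follow the axis order (x, y, z): e.g. "HLL" is high-pass along
#' x, low-pass along y and z.
#'
#' @param volume 3D numeric array; every axis must be at least as long as
#'   the filter (6 taps, coiflet-1).
#' @return named list of 8 arrays: LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH.
#' @export
wavelet_subbands <- function(volume) {
  d <- dim(volume)
  stopifnot(length(d) == 3)
  f <- coif1_filters()
  if (any(d < length(f$lo)))
    stop("volume too small for the wavelet filter length")
  out <- .cpp_swt3(as.numeric(volume), as.integer(d), f$lo, f$hi)
  lapply(out, function(v) { dim(v) <- d; v })
}

gaussian_smooth <- function(volume, sigma_voxels) {
  d <- dim(volume)
  if (length(d) == 2) d <- c(d, 1L)
  v <- .cpp_gaussian_smooth3(as.numeric(volume), as.integer(d),
                             as.numeric(sigma_voxels))
  dim(v) <- dim(volume)
  v
}
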