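# Cascaded segmentation orchestration: slice-wise localization (OR-reduced
# slice masks -> connected-component centres), nested cropping around each
# candidate lesion, then volumetric segmentation of the final crop by two
# pluggable backends whose probability maps are averaged and thresholded.
# Deep backends are out of scope; a classical smoothed-intensity/Otsu
# backend is provided for desk-scale use, and oracle backends (returning
# ground truth as probabilities) support exact tests.

#' Cascade configuration
#'
#' @param crop_sizes strictly decreasing in-plane window sizes, full
#'   grid -> mid crop -> final cubic crop (desk-scale default 64, 32, 32,
#'   proportional to clinical 512 -> 256 -> 128).
#' @param fusion_threshold probability threshold on the averaged maps.
#' @return list of class `cascade_config`.
#' @export
cascade_config <- function(crop_sizes = c(64L, 32L, 32L),
                           fusion_threshold = 0.5) {
  stopifnot(length(crop_sizes) == 3, all(diff(crop_sizes) <= 0),
            fusion_threshold > 0, fusion_threshold < 1)
  structure(list(crop_sizes = as.integer(crop_sizes),
                 fusion_threshold = fusion_threshold),
            class = "cascade_config")
}

#' OR-reduction of a stack of 2D slice masks
#'
#' Pixel true iff true in any slice: the upper bound of the lesion areas
#' across slices, used to localize candidates.
#'
#' @param slice_masks list of logical 2D matrices of equal shape, or a 3D
#'   logical array (slices along the third axis).
#' @return logical 2D matrix.
#' @export
or_reduce_slices <- function(slice_masks) {
  if (is.array(slice_masks) && length(dim(slice_masks)) == 3) {
    if (dim(slice_masks)[3] == 0) stop("empty slice stack")
    return(apply(slice_masks, c(1, 2), any))
  }
  if (length(slice_masks) == 0) stop("empty slice stack")
  d <- dim(slice_masks[[1]])
  out <- matrix(FALSE, d[1], d[2])
  for (s in slice_masks) {
    stopifnot(identical(dim(s), d))
    out <- out | s
  }
  out
}

#' Centres of the connected components of a 2D mask
#'
#' One centre per 8-connected component: the component centroid rounded to
#' the nearest pixel (`floor(x + 0.5)` per axis).
#'
#' @param mask logical 2D matrix.
#' @return matrix with columns `x`, `y` (one row per component); zero rows
#'   for an empty mask.
#' @export
component_centres <- function(mask) {
  lab <- label_components(mask, connectivity = 26)  # 8-connectivity in 2D
  ks <- setdiff(sort(unique(as.vector(lab))), 0)
  out <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
  for (k in ks) {
    co <- which(lab == k, arr.ind = TRUE)
    out <- rbind(out, floor(colMeans(co) + 0.5))
  }
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

#' Crop a window of fixed size about a centre
#'
#' The window always has exactly the requested size: near a volume face it
#' is shifted inward (clamped) rather than padded. The returned offset
#' allows exact back-placement into the full grid.
#'
#' @param volume 2D or 3D array.
#' @param centre numeric centre (one entry per axis).
#' @param size window size per axis (scalar recycled).
#' @return list with `crop` and `offset` (1-based start index per axis).
#' @export
crop_about <- function(volume, centre, size) {
  d <- dim(volume)
  if (length(size) == 1) size <- rep(size, length(d))
  if (any(size > d)) stop("crop size exceeds volume shape")
  start <- pmin(pmax(round(centre) - floor(size / 2), 1), d - size + 1)
  idx <- lapply(seq_along(d), function(a) start[a]:(start[a] + size[a] - 1))
  list(crop = do.call(`[`, c(list(volume), idx, list(drop = FALSE))),
       offset = as.integer(start))
}

#' Place a crop back into a full-size grid
#'
#' @param crop array returned by [crop_about()].
#' @param offset its offset record.
#' @param full_dim dimensions of the full grid.
#' @param fill background value.
#' @return full-size array, `crop` inside the window, `fill` outside.
#' @export
uncrop <- function(crop, offset, full_dim, fill = FALSE) {
  out <- array(fill, full_dim)
  d <- dim(crop)
  idx <- lapply(seq_along(full_dim),
                function(a) offset[a]:(offset[a] + d[a] - 1))
  ex <- do.call(`[<-`, c(list(out), idx, list(value = crop)))
  ex
}

#' Fuse two probability maps by averaging and thresholding
#'
#' Voxel foreground iff `(p1 + p2) / 2 >= threshold`.
#'
#' @param p1,p2 arrays of probabilities in `[0, 1]`, same shape.
#' @param threshold fusion threshold (default 0.5).
#' @param spacing_mm voxel spacing for the returned mask.
#' @return [binary_mask()].
#' @export
fuse_probability_maps <- function(p1, p2, threshold = 0.5,
                                  spacing_mm = c(0.5, 0.5, 0.5)) {
  if (!identical(dim(p1), dim(p2))) stop("probability map shapes differ")
  stopifnot(min(p1, p2) >= 0, max(p1, p2) <= 1)
  binary_mask((p1 + p2) / 2 >= threshold, spacing_mm)
}

#' Classical slice segmenter (smoothed intensity + Otsu)
#'
#' Returns a backend closure mapping a 2D image to a probability map:
#' Gaussian smoothing followed by a soft sigmoid around the Otsu
#' threshold. Pure, deterministic, desk-scale stand-in for a learned
#' slice segmenter.
#'
#' @param sigma smoothing in pixels.
#' @param sharpness sigmoid steepness (in units of the intensity range).
#' @param min_separation minimum Otsu class-mean separation (as a
#'   fraction of the slice range) for a slice to count as containing
#'   foreground; below it the slice yields zero probability everywhere.
#'   Guards against thresholding pure background noise into spurious
#'   components.
#' @return function(image2d) -> probability matrix.
#' @export
classical_slice_segmenter <- function(sigma = 1, sharpness = 12,
                                      min_separation = 0.45) {
  function(img) {
    sm <- gaussian_smooth(img, sigma)
    rng <- max(diff(range(sm)), 1e-9)
    thr <- otsu_threshold(sm)
    fg <- sm >= thr
    if (!any(fg) || all(fg) ||
        (mean(sm[fg]) - mean(sm[!fg])) / rng < min_separation)
      return(array(0, dim(img)))
    stats::plogis(sharpness * (sm - thr) / rng)
  }
}

#' Classical volume segmenter
#'
#' 3D analogue of [classical_slice_segmenter()]; accepts a two-channel
#' crop (list with `T1`, `T2`) and segments on the mean channel.
#'
#' @inheritParams classical_slice_segmenter
#' @return function(list(T1, T2)) -> probability array.
#' @export
classical_volume_segmenter <- function(sigma = 1, sharpness = 12) {
  function(channels) {
    img <- (channels$T1 + channels$T2) / 2
    sm <- gaussian_smooth(img, sigma)
    thr <- otsu_threshold(sm)
    stats::plogis(sharpness * (sm - thr) / max(diff(range(sm)), 1e-9))
  }
}

otsu_threshold <- function(x, n_bins = 128) {
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  h <- tabulate(pmin(as.integer((x - r[1]) / (r[2] - r[1]) * n_bins) + 1L,
                     n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + k / n_bins * (r[2] - r[1])
}

#' Run the cascaded segmentation over a study
#'
#' Slice masks from `slice_seg` (thresholded at 0.5) are OR-reduced to
#' localize candidate lesions; each candidate is cropped in-plane
#' (`crop_sizes[2]`), re-localized, then cropped to the final cubic
#' window (`crop_sizes[3]`) centred on the refined (x, y) and the
#' mask-weighted z centre. Both volume backends segment the two-channel
#' final crop; their probability maps are averaged, thresholded, restricted
#' to the component at the crop centre, and placed back into the full
#' grid. Lesions are treated separately: one output mask per detected
#' component.
#'
#' @param study imaging study (fields `channel_T1`, `channel_T2FLAIR`,
#'   `spacing_mm`).
#' @param slice_seg function(2D image) -> probability matrix.
#' @param vol_seg_a,vol_seg_b functions(list(T1, T2)) -> probability
#'   array.
#' @param config a [cascade_config()].
#' @return list of [binary_mask()] (possibly empty when nothing is
#'   detected), each with attribute `provenance` (component centre and
#'   crop offsets).
#' @export
run_cascade <- function(study, slice_seg,
                        vol_seg_a = classical_volume_segmenter(),
                        vol_seg_b = classical_volume_segmenter(sigma = 2),
                        config = cascade_config()) {
  vol <- study$channel_T1
  d <- dim(vol)
  stopifnot(all(config$crop_sizes <= max(d)))
  # stage 1: localize on the full grid
  p_slices <- vapply(seq_len(d[3]),
                     function(k) slice_seg(vol[, , k]) >= 0.5,
                     logical(d[1] * d[2]))
  dim(p_slices) <- d
  centres <- component_centres(or_reduce_slices(p_slices))
  out <- list()
  for (ci in seq_len(nrow(centres))) {
    cen <- centres[ci, ]
    # stage 2: mid in-plane crop, refined localization
    mid <- crop_about(vol, c(cen, (d[3] + 1) / 2),
                      c(config$crop_sizes[2], config$crop_sizes[2], d[3]))
    md <- dim(mid$crop)
    m_slices <- vapply(seq_len(md[3]),
                       function(k) slice_seg(mid$crop[, , k]) >= 0.5,
                       logical(md[1] * md[2]))
    dim(m_slices) <- md
    or2 <- or_reduce_slices(m_slices)
    c2 <- component_centres(or2)
    if (nrow(c2) == 0) next
    # nearest refined centre to the crop centre
    cc <- c2[which.min(rowSums(sweep(c2, 2, md[1:2] / 2)^2)), ]
    # z centre from the mask profile in a small in-plane window around the
    # refined centre, so off-lesion false positives cannot drag the crop
    wx <- max(1, cc[1] - 3):min(md[1], cc[1] + 3)
    wy <- max(1, cc[2] - 3):min(md[2], cc[2] + 3)
    zw <- apply(m_slices[wx, wy, , drop = FALSE], 3, sum)
    zc <- if (sum(zw) > 0) sum(seq_len(md[3]) * zw) / sum(zw) else md[3] / 2
    centre_full <- c(mid$offset[1:2] - 1 + cc, mid$offset[3] - 1 + zc)
    # stage 3: final cubic crop, two-channel volumetric segmentation
    fin <- crop_about(vol, centre_full, config$crop_sizes[3])
    fin2 <- crop_about(study$channel_T2FLAIR, centre_full,
                       config$crop_sizes[3])
    channels <- list(T1 = fin$crop, T2 = fin2$crop)
    # crop provenance travels with the input so oracle backends can look
    # up reference voxels; classical backends ignore it
    attr(channels, "offset") <- fin$offset
    fused <- fuse_probability_maps(vol_seg_a(channels), vol_seg_b(channels),
                                   config$fusion_threshold, study$spacing_mm)
    if (!any(fused$voxels)) next
    # keep the component covering the crop centre (fall back to largest)
    lab <- label_components(fused$voxels, connectivity = 26)
    mid_idx <- pmax(1, pmin(dim(lab), round(dim(lab) / 2)))
    k0 <- lab[mid_idx[1], mid_idx[2], mid_idx[3]]
    keep <- if (k0 > 0) lab == k0 else
      lab == which.max(tabulate(lab[lab > 0]))
    full <- uncrop(keep, fin$offset, d)
    m <- binary_mask(full, study$spacing_mm)
    attr(m, "provenance") <- list(centre = centre_full,
                                  mid_offset = mid$offset,
                                  final_offset = fin$offset)
    out[[length(out) + 1]] <- m
  }
  out
}
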