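#' Extraction configuration
#'
#' @param n_bins gray levels for the equal-width discretization of each
#'   ROI (applied independently per image: wavelet sub-band ranges differ
#'   from the normalized `[0, 1]` original).
#' @param margin_width_mm peritumoural margin width.
#' @param wavelet include the 8 stationary wavelet sub-bands.
#' @param gldm_alpha dependence tolerance for the GLDM family.
#' @param crop_pad extra voxels kept around the tumour+margin bounding box
#'   (absorbs wavelet wrap-around and mask perturbation).
#' @return list of class `extraction_config`.
#' @export
extraction_config <- function(n_bins = 32, margin_width_mm = 5,
                              wavelet = TRUE, gldm_alpha = 0,
                              crop_pad = 4L) {
  structure(list(n_bins = n_bins, margin_width_mm = margin_width_mm,
                 wavelet = wavelet, gldm_alpha = gldm_alpha,
                 crop_pad = as.integer(crop_pad)),
            class = "extraction_config")
}

intensity_family_fns <- function(cfg) {
  list(glcm = glcm_features,
       glrlm = glrlm_features,
       glszm = glszm_features,
       ngtdm = ngtdm_features,
       gldm = gldm_features)
}

# crop window (list of 3 index ranges) around a mask, padded and clamped
crop_window <- function(vox, pad, d) {
  co <- voxel_coords(vox)
  lapply(1:3, function(a) {
    lo <- max(1L, min(co[, a]) - pad)
    hi <- min(d[a], max(co[, a]) + pad)
    lo:hi
  })
}

crop_array <- function(arr, win) arr[win[[1]], win[[2]], win[[3]], drop = FALSE]

#' Build the per-lesion image stack (both modalities, original + wavelet)
#'
#' Normalizes each channel over the whole volume, crops a padded window
#' around the lesion, and computes the 8 stationary wavelet sub-bands per
#' modality. The stack is mask-independent, so degraded masks of the same
#' lesion can reuse it.
#'
#' @param study an imaging study (fields `channel_T1`, `channel_T2FLAIR`,
#'   `gt_masks`, `spacing_mm`).
#' @param lesion_id lesion whose ground-truth mask anchors the crop.
#' @param config an [extraction_config()].
#' @return list with `images` (named list `T1`/`T2`, each a named list of
#'   9 arrays), `window`, `spacing_mm`, `dim`.
#' @export
build_image_stack <- function(study, lesion_id, config = extraction_config()) {
  gt <- study$gt_masks[[lesion_id]]
  if (is.null(gt)) stop("unknown lesion id: ", lesion_id)
  d <- dim(study$channel_T1)
  margin_vox <- ceiling(config$margin_width_mm / study$spacing_mm[1])
  win <- crop_window(gt$voxels, margin_vox + config$crop_pad, d)
  images <- list()
  for (ch in c("T1", "T2")) {
    full <- if (ch == "T1") study$channel_T1 else study$channel_T2FLAIR
    norm <- normalize_unit(full)
    crop <- crop_array(norm$volume, win)
    imgs <- list(original = crop)
    if (config$wavelet) {
      wb <- wavelet_subbands(crop)
      names(wb) <- paste0("wavelet-", names(wb))
      imgs <- c(imgs, wb)
    }
    images[[ch]] <- imgs
  }
  list(images = images, window = win, spacing_mm = study$spacing_mm,
       dim = vapply(win, length, integer(1)))
}

#' Extract the full radiomic feature vector for one lesion at one timepoint
#'
#' The default configuration emits exactly 3436 named features: 94
#' intensity features (19 first-order + 24 GLCM + 16 GLRLM + 16 GLSZM +
#' 5 NGTDM + 14 GLDM) for each of 9 images (original + 8 wavelet
#' sub-bands), 2 modalities (T1, T2) and 2 ROIs (tumour, 5 mm margin),
#' plus 26 shape features per ROI computed from the mask alone. Names
#' follow `<image>_<family>_<feature>_<modality>[_Margin]`, e.g.
#' `wavelet-HHL_firstorder_Minimum_T1_Margin`; shape features use
#' `original_shape_<feature>[_Margin]`.
#'
#' @param study an imaging study.
#' @param mask lesion mask to extract from (a [binary_mask()] on the study
#'   grid); defaults to the ground-truth mask of `lesion_id`.
#' @param lesion_id lesion identifier (anchors the crop window).
#' @param config an [extraction_config()].
#' @param stack optional precomputed [build_image_stack()] result.
#' @return named numeric vector (3436 entries for the default config).
#' @export
extract_feature_vector <- function(study, lesion_id, mask = NULL,
                                   config = extraction_config(),
                                   stack = NULL) {
  if (is.null(stack)) stack <- build_image_stack(study, lesion_id, config)
  if (is.null(mask)) mask <- study$gt_masks[[lesion_id]]
  win <- stack$window
  vox <- crop_array(mask$voxels, win)
  if (!any(vox))
    stop("feature extraction failed: mask empty inside the crop window")
  tum <- binary_mask(vox, mask$spacing_mm)
  rois <- margin_mask(tum, config$margin_width_mm)
  extract_from_stack(stack, rois, config)
}

extract_from_stack <- function(stack, rois, config = extraction_config()) {
  fam_fns <- intensity_family_fns(config)
  out <- vector("list", 2 * (1 + 2 * 9 * 6))
  oi <- 0
  add <- function(v, nm) {
    oi <<- oi + 1
    names(v) <- nm
    out[[oi]] <<- v
  }
  roi_list <- stats::setNames(list(rois$tumour, rois$margin),
                              c("", "_Margin"))
  for (ri in seq_along(roi_list)) {
    suffix <- names(roi_list)[ri]
    roi <- roi_list[[ri]]
    sf <- shape_features(roi)
    add(sf, paste0("original_shape_", names(sf), suffix))
    idx <- which(roi$voxels)
    dm <- dim(roi$voxels)
    lev0 <- array(0L, dm)
    for (mod in c("T1", "T2")) {
      for (img_name in names(stack$images[[mod]])) {
        img <- stack$images[[mod]][[img_name]]
        vals <- img[idx]
        codes <- discretize_codes(vals, config$n_bins)
        fo <- first_order_from_vals(vals, codes, config$n_bins,
                                    stack$spacing_mm)
        add(fo, paste0(img_name, "_firstorder_", names(fo), "_", mod,
                       suffix))
        lev <- lev0
        lev[idx] <- codes
        disc <- list(levels = lev, n_bins = as.integer(config$n_bins))
        tm <- texture_matrices(disc, config$gldm_alpha)
        fam_args <- list(glcm = list(counts = tm$glcm),
                         glrlm = list(runs = tm$glrlm),
                         glszm = list(zones = tm$glszm),
                         ngtdm = list(M = tm$ngtdm),
                         gldm = list(alpha = config$gldm_alpha, M = tm$gldm))
        fam <- NULL  # reported on failure
        tryCatch(
          for (fam in names(fam_fns)) {
            fv <- do.call(fam_fns[[fam]], c(list(disc), fam_args[[fam]]))
            add(fv, paste0(img_name, "_", fam, "_", names(fv), "_", mod,
                           suffix))
          },
          error = function(e)
            stop(sprintf("family %s failed on ROI '%s' (%s %s): %s", fam,
                         if (suffix == "") "tumour" else "margin",
                         img_name, mod, conditionMessage(e)),
                 call. = FALSE))
      }
    }
  }
  unlist(out[seq_len(oi)])
}

#' Delta features between baseline and first follow-up
#'
#' Relative change per feature: `(fu1 - bl) / max(|bl|, eps)` with
#' `eps = 1e-12` guarding division by a vanishing baseline (the result is
#' finite and keeps the sign of the change).
#'
#' @param fv_bl,fv_fu1 named feature vectors with identical name sets.
#' @param eps baseline magnitude floor.
#' @return named numeric vector on the shared name set.
#' @export
delta_features <- function(fv_bl, fv_fu1, eps = 1e-12) {
  if (!identical(names(fv_bl), names(fv_fu1))) {
    if (!setequal(names(fv_bl), names(fv_fu1)))
      stop("baseline and follow-up feature name sets differ")
    fv_fu1 <- fv_fu1[names(fv_bl)]
  }
  (fv_fu1 - fv_bl) / pmax(abs(fv_bl), eps)
}

#' Expected feature count for a configuration
#'
#' Closed form `n_intensity * n_images * n_modalities * n_rois +
#' n_shape * n_rois`; 3436 for the default 94/9/2/2 + 26*2 layout.
#'
#' @param n_images images per modality (1 original + wavelet sub-bands).
#' @param n_modalities,n_rois modality and ROI counts.
#' @param n_intensity,n_shape family sizes.
#' @return integer feature count.
#' @export
expected_feature_count <- function(n_images = 9, n_modalities = 2,
                                   n_rois = 2, n_intensity = 94,
                                   n_shape = 26) {
  as.integer(n_intensity * n_images * n_modalities * n_rois +
               n_shape * n_rois)
}
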