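#' Configuration for a synthetic brain-metastasis imaging cohort
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: paired baseline (BL) / first follow-up (FU1) two-channel
#' volumes per patient, one ground-truth mask per lesion, class-dependent
#' lesion growth and texture change, and outcome-linked survival. Defaults
#' mirror a 124-patient / ~156-lesion cohort with a 93:63 local-control to
#' local-failure mix, split by patient into 89 train / 10 validation / 25
#' test.
#'
#' @param n_train_patients,n_val_patients,n_test_patients patients per
#'   split (split is always by patient, never by lesion).
#' @param lesions_per_patient integer range; lesion count per patient drawn
#'   uniformly.
#' @param lf_fraction probability a lesion is a local failure (LF).
#' @param volume_shape voxels per axis (desk-scale stand-in for clinical
#'   512x512x348 grids).
#' @param spacing_mm isotropic voxel size in mm.
#' @param lesion_radius_range baseline mean lesion radius range, voxels
#'   (radii must be at least 2 voxels).
#' @param lf_growth_factor_range FU1/BL volume ratio range for LF lesions.
#' @param lc_change_factor_range FU1/BL volume ratio range for LC lesions.
#' @param texture_effect_size dimensionless shift of the intra-lesion
#'   texture regime (correlation length and variance) for LF lesions at
#'   FU1; 0 removes the texture signal entirely.
#' @param noise_sd white-noise standard deviation, as a fraction of the
#'   image dynamic range.
#' @param margin_width_mm peritumoural margin width used for placement
#'   buffering and downstream extraction.
#' @param hazard_lc monthly progression hazard for patients with only LC
#'   lesions.
#' @param hazard_ratio_lf hazard ratio applied when a patient bears at
#'   least one LF lesion.
#' @param censor_time administrative censoring horizon, months.
#' @param seed integer master seed; all generator output is a pure
#'   function of the configuration including this seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_train_patients = 89L, n_val_patients = 10L,
                          n_test_patients = 25L,
                          lesions_per_patient = c(1L, 2L),
                          lf_fraction = 63 / 156,
                          volume_shape = c(64L, 64L, 64L),
                          spacing_mm = 0.5,
                          lesion_radius_range = c(3, 6),
                          lf_growth_factor_range = c(1.2, 2.0),
                          lc_change_factor_range = c(0.5, 1.1),
                          texture_effect_size = 0.5,
                          noise_sd = 0.05,
                          margin_width_mm = 5,
                          hazard_lc = 0.05,
                          hazard_ratio_lf = 4,
                          censor_time = 24,
                          seed = 1L) {
  cfg <- list(n_train_patients = as.integer(n_train_patients),
              n_val_patients = as.integer(n_val_patients),
              n_test_patients = as.integer(n_test_patients),
              lesions_per_patient = as.integer(lesions_per_patient),
              lf_fraction = lf_fraction,
              volume_shape = as.integer(volume_shape),
              spacing_mm = spacing_mm,
              lesion_radius_range = lesion_radius_range,
              lf_growth_factor_range = lf_growth_factor_range,
              lc_change_factor_range = lc_change_factor_range,
              texture_effect_size = texture_effect_size,
              noise_sd = noise_sd,
              margin_width_mm = margin_width_mm,
              hazard_lc = hazard_lc,
              hazard_ratio_lf = hazard_ratio_lf,
              censor_time = censor_time,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_train_patients >= 1, cfg$n_test_patients >= 0,
            cfg$n_val_patients >= 0)
  if (cfg$lf_fraction < 0 || cfg$lf_fraction > 1)
    stop("lf_fraction must lie in [0, 1]")
  ranges <- list(cfg$lesions_per_patient, cfg$lesion_radius_range,
                 cfg$lf_growth_factor_range, cfg$lc_change_factor_range)
  for (r in ranges)
    if (length(r) != 2 || r[1] > r[2]) stop("ranges must satisfy low <= high")
  if (cfg$lesion_radius_range[1] < 2)
    stop("lesion radii must be at least 2 voxels")
  # the largest possible FU1 lesion plus its margin must fit in the grid
  max_r <- max_lesion_extent(cfg)
  if (2 * (max_r + 1) >= min(cfg$volume_shape))
    stop(sprintf(paste0("lesions cannot fit: maximum lesion+margin extent ",
                        "%.1f voxels exceeds volume shape %d"),
                 2 * max_r, min(cfg$volume_shape)))
  invisible(cfg)
}

# worst-case lesion radius (voxels) incl. anisotropy, growth and margin
max_lesion_extent <- function(cfg) {
  margin_vox <- cfg$margin_width_mm / cfg$spacing_mm
  max(cfg$lesion_radius_range) * 1.15 *
    max(cfg$lf_growth_factor_range, 1)^(1 / 3) + margin_vox
}

# texture regimes: interior Gaussian random field parameters per channel,
# margin shell gets a distinct, shorter-range regime
default_texture_params <- function() {
  list(corr_len = 2.0, sd = 0.15, contrast = c(T1 = 0.6, T2 = 0.4),
       margin_corr_len = 1.0, margin_sd = 0.10,
       margin_contrast = c(T1 = 0.15, T2 = 0.25))
}

#' Render one ellipsoidal lesion into a volume grid
#'
#' Phantom construction: the mask is the discretized ellipsoid; interior
#' intensities are a Gaussian random field (smoothed white noise with
#' correlation length `texture_params$corr_len`, standard deviation
#' `texture_params$sd`) on top of a constant contrast plateau, and the
#' margin shell around the lesion receives a distinct texture regime so
#' peritumoural features are informative.
#'
#' @param centre numeric length-3 lesion centre (voxel coordinates).
#' @param radii numeric length-3 ellipsoid radii in voxels (all >= 2).
#' @param texture_params list with `corr_len`, `sd`, `contrast`,
#'   `margin_corr_len`, `margin_sd`, `margin_contrast` (see
#'   `default_texture_params`); contrasts are per-channel named vectors.
#' @param channel "T1" or "T2" (selects the contrast entries).
#' @param volume_shape integer length-3 grid shape.
#' @param spacing_mm isotropic voxel size (mm).
#' @param margin_width_mm width of the textured shell around the mask.
#' @param seed integer seed; same seed reproduces the sub-volume exactly.
#' @return list with `volume` (additive intensity contribution over the
#'   full grid) and `mask` ([binary_mask()]).
#' @export
render_lesion <- function(centre, radii, texture_params = default_texture_params(),
                          channel = "T1", volume_shape = c(64L, 64L, 64L),
                          spacing_mm = 0.5, margin_width_mm = 5, seed = 1L) {
  if (any(radii < 2)) stop("lesion radii below 2 voxels are rejected")
  d <- as.integer(volume_shape)
  if (any(centre - radii < 1) || any(centre + radii > d))
    stop("ellipsoid does not lie inside the volume")
  margin_vox <- margin_width_mm / spacing_mm
  # all texture lives inside lesion + shell: work on that local box only
  ext <- radii * sqrt((1 + margin_vox / mean(radii))^2) + 2
  lo <- pmax(1L, as.integer(floor(centre - ext)))
  hi <- pmin(d, as.integer(ceiling(centre + ext)))
  bd <- hi - lo + 1L
  ax <- lo[1]:hi[1]; ay <- lo[2]:hi[2]; az <- lo[3]:hi[3]
  # squared normalized ellipsoid coordinate on the box
  q <- outer(outer((ax - centre[1])^2 / radii[1]^2,
                   (ay - centre[2])^2 / radii[2]^2, `+`),
             (az - centre[3])^2 / radii[3]^2, `+`)
  mask_box <- q <= 1
  # approximate shell in normalized coordinates (exact margin geometry is
  # recomputed downstream by the distance transform; here it only needs to
  # receive a distinct texture)
  shell_q <- (1 + margin_vox / mean(radii))^2
  shell <- q > 1 & q <= shell_q
  tex <- with_seed(seed, {
    g1 <- gaussian_smooth(array(rnorm(prod(bd)), bd),
                          texture_params$corr_len)
    g2 <- gaussian_smooth(array(rnorm(prod(bd)), bd),
                          texture_params$margin_corr_len)
    list(inner = g1 / stats::sd(g1), outer = g2 / stats::sd(g2))
  })
  box <- array(0, bd)
  box[mask_box] <- texture_params$contrast[[channel]] +
    texture_params$sd * tex$inner[mask_box]
  # taper the shell contribution with distance so lesions do not imprint
  # hard rings on the background
  taper <- pmax(0, 1 - (sqrt(q[shell]) - 1) * mean(radii) / margin_vox)
  box[shell] <- (texture_params$margin_contrast[[channel]] +
                   texture_params$margin_sd * tex$outer[shell]) * taper
  vol <- array(0, d)
  vol[ax, ay, az] <- box
  mask <- array(FALSE, d)
  mask[ax, ay, az] <- mask_box
  list(volume = vol,
       mask = binary_mask(mask, rep(spacing_mm, 3)))
}

# draw per-lesion geometry and class parameters
draw_lesion_params <- function(cfg, outcome, seed) {
  with_seed(seed, {
    base_r <- runif(1, cfg$lesion_radius_range[1], cfg$lesion_radius_range[2])
    aniso <- runif(3, 0.85, 1.15)
    growth <- if (outcome == "LF")
      runif(1, cfg$lf_growth_factor_range[1], cfg$lf_growth_factor_range[2])
    else
      runif(1, cfg$lc_change_factor_range[1], cfg$lc_change_factor_range[2])
    list(radii_bl = base_r * aniso, growth = growth,
         radii_fu1 = base_r * aniso * growth^(1 / 3))
  })
}

place_lesions <- function(cfg, params_list, seed) {
  # rejection-sample centres so lesions (at their largest extent) stay
  # inside the grid with a margin buffer and remain pairwise disjoint
  d <- cfg$volume_shape
  margin_vox <- cfg$margin_width_mm / cfg$spacing_mm
  with_seed(seed, {
    centres <- list()
    for (i in seq_along(params_list)) {
      r_max <- max(params_list[[i]]$radii_bl, params_list[[i]]$radii_fu1)
      buf <- r_max + margin_vox / 2 + 1
      lo <- rep(ceiling(buf + 1), 3); hi <- floor(d - buf)
      if (any(lo > hi))
        stop("lesion cannot fit in the volume with the required buffer")
      ok <- FALSE
      for (try in 1:200) {
        c_i <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]),
                 runif(1, lo[3], hi[3]))
        sep <- TRUE
        for (j in seq_along(centres)) {
          r_j <- max(params_list[[j]]$radii_bl, params_list[[j]]$radii_fu1)
          if (sqrt(sum((c_i - centres[[j]])^2)) < r_max + r_j + 4) {
            sep <- FALSE
            break
          }
        }
        if (sep) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place disjoint lesions in the volume")
      centres[[i]] <- c_i
    }
    centres
  })
}

lesion_texture_params <- function(cfg, outcome, timepoint) {
  tp <- default_texture_params()
  if (outcome == "LF" && timepoint == "FU1" && cfg$texture_effect_size > 0) {
    e <- cfg$texture_effect_size
    tp$corr_len <- tp$corr_len * (1 + e)
    tp$sd <- tp$sd * (1 + 0.5 * e)
    tp$margin_sd <- tp$margin_sd * (1 + 0.5 * e)
  }
  tp
}

#' Generate a complete synthetic cohort
#'
#' Produces paired BL/FU1 two-channel studies for every patient, lesion
#' records with true outcomes and volumes, outcome-linked survival
#' records, and a patient-level train/validation/test split. Regenerating
#' with the same configuration reproduces identical output.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `studies` (named
#'   `"<patient>_<timepoint>"`), `lesions` (data frame), `survival` (data
#'   frame), and `split` (data frame patient_id/split).
#' @export
generate_cohort <- function(config = cohort_config()) {
  cfg <- config
  n_pat <- cfg$n_train_patients + cfg$n_val_patients + cfg$n_test_patients
  patient_ids <- sprintf("P%03d", seq_len(n_pat))
  split <- data.frame(
    patient_id = patient_ids,
    split = rep(c("train", "val", "test"),
                c(cfg$n_train_patients, cfg$n_val_patients,
                  cfg$n_test_patients)),
    stringsAsFactors = FALSE)

  studies <- list()
  lesion_rows <- list()
  d <- cfg$volume_shape
  for (p in seq_len(n_pat)) {
    pid <- patient_ids[p]
    pseed <- child_seed(cfg$seed, "patient", pid)
    n_les <- with_seed(pseed, sample(
      seq(cfg$lesions_per_patient[1], cfg$lesions_per_patient[2]), 1))
    outcomes <- with_seed(child_seed(pseed, "outcome"),
                          ifelse(runif(n_les) < cfg$lf_fraction, "LF", "LC"))
    params <- lapply(seq_len(n_les), function(l)
      draw_lesion_params(cfg, outcomes[l], child_seed(pseed, "geom", l)))
    centres <- place_lesions(cfg, params, child_seed(pseed, "place"))

    # smooth anatomical background per channel, shared between timepoints
    # (same patient anatomy); generated on a 4x coarser lattice and
    # trilinearly upsampled
    backgrounds <- lapply(c(T1 = "T1", T2 = "T2"), function(ch)
      with_seed(child_seed(pseed, "background", ch), {
        cd <- as.integer(ceiling(d / 4) + 1)
        bg <- gaussian_smooth(array(rnorm(prod(cd)), cd), 1.5)
        up <- .cpp_resample(as.numeric(bg), cd, rep(4, 3), rep(1, 3),
                            as.integer(cd * 4L), FALSE)
        dim(up) <- cd * 4L
        up <- up[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
        0.25 + 0.05 * up / stats::sd(up)
      }))
    for (tp in c("BL", "FU1")) {
      chans <- list()
      gt_masks <- list()
      for (ch in c("T1", "T2")) {
        vol <- backgrounds[[ch]]
        for (l in seq_len(n_les)) {
          radii <- if (tp == "BL") params[[l]]$radii_bl else
            params[[l]]$radii_fu1
          tex <- lesion_texture_params(cfg, outcomes[l], tp)
          # texture field seed shared between timepoints only through the
          # lesion id so BL and FU1 fields differ (independent scans)
          rl <- render_lesion(centres[[l]], radii, tex, ch, d,
                              cfg$spacing_mm, cfg$margin_width_mm,
                              seed = child_seed(pseed, "texture", l, tp, ch))
          vol <- vol + rl$volume
          if (ch == "T1") gt_masks[[sprintf("%s_L%d", pid, l)]] <- rl$mask
        }
        vol <- vol + with_seed(child_seed(pseed, "noise", ch, tp),
                               array(rnorm(prod(d), sd = cfg$noise_sd), d))
        chans[[ch]] <- vol
      }
      studies[[paste(pid, tp, sep = "_")]] <- structure(
        list(patient_id = pid, timepoint = tp,
             lesion_ids = names(gt_masks),
             channel_T1 = chans$T1, channel_T2FLAIR = chans$T2,
             gt_masks = gt_masks,
             spacing_mm = rep(cfg$spacing_mm, 3)),
        class = "imaging_study")
    }
    for (l in seq_len(n_les)) {
      lid <- sprintf("%s_L%d", pid, l)
      bl_m <- studies[[paste(pid, "BL", sep = "_")]]$gt_masks[[lid]]
      fu_m <- studies[[paste(pid, "FU1", sep = "_")]]$gt_masks[[lid]]
      lesion_rows[[lid]] <- data.frame(
        lesion_id = lid, patient_id = pid, true_outcome = outcomes[l],
        bl_volume_cc = mask_volume_cc(bl_m),
        fu1_volume_cc = mask_volume_cc(fu_m),
        growth_factor = params[[l]]$growth,
        stringsAsFactors = FALSE)
    }
  }
  lesions <- do.call(rbind, lesion_rows)
  rownames(lesions) <- NULL
  survival <- assign_survival(lesions, cfg$hazard_lc, cfg$hazard_ratio_lf,
                              cfg$censor_time,
                              seed = child_seed(cfg$seed, "survival"))
  structure(list(studies = studies, lesions = lesions, survival = survival,
                 split = split, config = cfg),
            class = "synthetic_cohort")
}

#' Draw outcome-linked progression-free survival records
#'
#' Patient-level exponential times with proportional hazards: a patient's
#' hazard is `hazard_lc * hazard_ratio_lf^(any lesion LF)`. Times beyond
#' `censor_time` are administratively censored at that horizon.
#'
#' @param lesion_records data frame with `patient_id` and `true_outcome`.
#' @param hazard_lc baseline monthly hazard (> 0).
#' @param hazard_ratio_lf hazard ratio for LF-bearing patients (> 0).
#' @param censor_time censoring horizon in months.
#' @param seed integer seed.
#' @return data frame with `patient_id`, `pfs_time`, `event` (1 =
#'   progressed, 0 = censored).
#' @export
assign_survival <- function(lesion_records, hazard_lc = 0.05,
                            hazard_ratio_lf = 4, censor_time = 24,
                            seed = 1L) {
  stopifnot(hazard_lc > 0, hazard_ratio_lf > 0)
  pats <- unique(lesion_records$patient_id)
  any_lf <- vapply(pats, function(p)
    any(lesion_records$true_outcome[lesion_records$patient_id == p] == "LF"),
    logical(1))
  hz <- hazard_lc * hazard_ratio_lf^as.numeric(any_lf)
  times <- with_seed(seed, rexp(length(pats), rate = hz))
  event <- as.integer(times <= censor_time)
  data.frame(patient_id = pats,
             pfs_time = pmin(times, censor_time),
             event = event,
             row.names = NULL, stringsAsFactors = FALSE)
}
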