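# Synthetic cohort generator: determinism, class structure, geometry and
# survival.

test_that("cohort configuration validates its invariants", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(lf_fraction = 1.5), "lf_fraction")
  expect_error(cohort_config(lesion_radius_range = c(1, 5)), "at least 2")
  expect_error(cohort_config(lesion_radius_range = c(6, 3)), "low <= high")
  # lesions that cannot fit inside the grid are rejected up front
  expect_error(cohort_config(volume_shape = c(24L, 24L, 24L)),
               "cannot fit")
})

test_that("same seed reproduces bit-identical volumes and labels", {
  cfg <- cohort_config(n_train_patients = 2L, n_val_patients = 1L,
                       n_test_patients = 1L, seed = 7L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$studies[[1]]$channel_T1, c2$studies[[1]]$channel_T1)
  expect_identical(c1$studies[[3]]$channel_T2FLAIR,
                   c2$studies[[3]]$channel_T2FLAIR)
  expect_identical(c1$lesions, c2$lesions)
  expect_identical(c1$survival, c2$survival)
  # a different seed changes the voxel data
  c3 <- generate_cohort(cohort_config(n_train_patients = 2L,
                                      n_val_patients = 1L,
                                      n_test_patients = 1L, seed = 8L))
  expect_false(identical(c1$studies[[1]]$channel_T1,
                         c3$studies[[1]]$channel_T1))
})

test_that("degenerate class mix: lf_fraction 0 gives only LC lesions", {
  cfg <- cohort_config(n_train_patients = 3L, n_val_patients = 0L,
                       n_test_patients = 1L, lf_fraction = 0, seed = 3L)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$lesions$true_outcome == "LC"))
})

test_that("cohort structure: paired studies, patient-level split, masks", {
  coh <- shared_cohort()
  cfg <- coh$config
  n_pat <- cfg$n_train_patients + cfg$n_val_patients + cfg$n_test_patients
  expect_length(coh$studies, 2 * n_pat)
  # split is a partition of the patients
  expect_setequal(coh$split$patient_id, unique(coh$lesions$patient_id))
  expect_equal(as.vector(table(coh$split$split)[c("test", "train", "val")]),
               c(cfg$n_test_patients, cfg$n_train_patients,
                 cfg$n_val_patients))
  expect_false(any(duplicated(coh$split$patient_id)))
  for (pid in coh$split$patient_id) {
    bl <- coh$studies[[paste0(pid, "_BL")]]
    fu <- coh$studies[[paste0(pid, "_FU1")]]
    expect_false(is.null(bl)); expect_false(is.null(fu))
    expect_setequal(bl$lesion_ids, fu$lesion_ids)
    expect_identical(dim(bl$channel_T1), dim(bl$channel_T2FLAIR))
    # ground-truth masks non-empty and pairwise disjoint
    msum <- Reduce(`+`, lapply(bl$gt_masks, function(m) m$voxels))
    expect_lte(max(msum), 1)
    for (m in bl$gt_masks) expect_gt(sum(m$voxels), 0)
  }
})

test_that("FU1/BL mask volume ratio tracks the drawn growth factor", {
  coh <- shared_cohort()
  les <- coh$lesions
  ratio <- les$fu1_volume_cc / les$bl_volume_cc
  # discretization error bound: one voxel layer on the BL radius
  r_vox <- (3 * les$bl_volume_cc * 1000 / (4 * pi))^(1 / 3) / 0.5
  bound <- ((r_vox + 1) / r_vox)^3 - 1
  expect_true(all(abs(ratio - les$growth_factor) <=
                    les$growth_factor * bound))
  # LF lesions grow
  lf <- les$true_outcome == "LF"
  expect_true(all(les$fu1_volume_cc[lf] > les$bl_volume_cc[lf]))
})

test_that("LF prevalence is consistent with the configured rate", {
  coh <- shared_cohort()
  extra <- generate_cohort(cohort_config(n_train_patients = 16L,
                                         n_val_patients = 0L,
                                         n_test_patients = 0L, seed = 9L))
  n_lf <- sum(coh$lesions$true_outcome == "LF") +
    sum(extra$lesions$true_outcome == "LF")
  n <- nrow(coh$lesions) + nrow(extra$lesions)
  p <- coh$config$lf_fraction
  ci <- qbinom(c(0.025, 0.975), n, p)
  expect_gte(n_lf, ci[1])
  expect_lte(n_lf, ci[2])
})

test_that("render_lesion: lattice-count oracle, determinism, rejections", {
  d <- c(32L, 32L, 32L)
  out <- render_lesion(c(16, 16, 16), c(5, 5, 5), channel = "T1",
                       volume_shape = d, seed = 5)
  ax <- 1:32
  q <- outer(outer((ax - 16)^2, (ax - 16)^2, `+`), (ax - 16)^2, `+`)
  expect_equal(sum(out$mask$voxels), sum(q <= 25))
  out2 <- render_lesion(c(16, 16, 16), c(5, 5, 5), channel = "T1",
                        volume_shape = d, seed = 5)
  expect_identical(out$volume, out2$volume)
  expect_error(render_lesion(c(16, 16, 16), c(1.5, 5, 5),
                             volume_shape = d, seed = 1), "below 2")
  expect_error(render_lesion(c(3, 16, 16), c(5, 5, 5),
                             volume_shape = d, seed = 1), "inside")
})

test_that("zero texture effect leaves LF and LC interiors indistinguishable", {
  # pooled interior intensities of FU1 LF vs FU1 LC lesions rendered with
  # the same texture regime must pass a two-sample KS test
  # draws inside one lesion are spatially correlated (the field has a
  # 2-voxel correlation length), which would wreck the KS calibration on
  # full pools; a handful of voxels from each of many lesions gives
  # approximately independent draws
  pool <- function(outcome) {
    vals <- c()
    for (s in 1:30) {
      tex <- radrobust:::default_texture_params()
      out <- render_lesion(c(16, 16, 16), c(5, 5, 5), tex, "T1",
                           c(32L, 32L, 32L), seed = s * 131 +
                             (outcome == "LF"))
      v <- out$volume[out$mask$voxels]
      set.seed(s + 7 * (outcome == "LF"))
      vals <- c(vals, sample(v, 4))
    }
    vals
  }
  ks <- suppressWarnings(ks.test(pool("LF"), pool("LC")))
  expect_gt(ks$p.value, 0.01)
})

test_that("assign_survival: hazards, censoring and closed-form median", {
  recs <- data.frame(patient_id = sprintf("P%04d", 1:1000),
                     true_outcome = rep(c("LC", "LF"), 500))
  # all LF-bearing patients at hazard 0.05 * 4 = 0.2: KM median ~ ln2/0.2
  sv <- assign_survival(recs, hazard_lc = 0.05, hazard_ratio_lf = 4,
                        censor_time = 1e6, seed = 21)
  lf_pat <- recs$patient_id[recs$true_outcome == "LF"]
  med <- median(sv$pfs_time[sv$patient_id %in% lf_pat])
  expect_equal(med, log(2) / 0.2, tolerance = 0.1)
  med_lc <- median(sv$pfs_time[!sv$patient_id %in% lf_pat])
  expect_equal(med_lc, log(2) / 0.05, tolerance = 0.1)

  # tiny censor horizon: everything censored at the horizon
  sv0 <- assign_survival(recs, 0.0001, 1, censor_time = 1e-8, seed = 2)
  expect_true(all(sv0$event == 0))
  expect_true(all(sv0$pfs_time == 1e-8))
  expect_error(assign_survival(recs, -1, 2), "hazard")
})

test_that("null hazard ratio gives a calibrated log-rank statistic", {
  recs <- data.frame(patient_id = sprintf("P%03d", 1:60),
                     true_outcome = rep(c("LC", "LF"), 30))
  lf_pat <- recs$patient_id[recs$true_outcome == "LF"]
  stats <- vapply(1:50, function(s) {
    sv <- assign_survival(recs, 0.05, hazard_ratio_lf = 1,
                          censor_time = 24, seed = s)
    logrank_test(sv$pfs_time, sv$event,
                 sv$patient_id %in% lf_pat)$statistic
  }, numeric(1))
  # chi-square(1) has mean 1
  expect_gt(mean(stats), 0.5)
  expect_lt(mean(stats), 1.7)
})
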