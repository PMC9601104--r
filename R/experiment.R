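#' Segmentation quality levels for the robustness study
#'
#' The default ladder mirrors the test-set baseline Dice of the four
#' segmentation models the study emulates (0.85, 0.85, 0.88, 0.90) plus
#' the ground truth; duplicated values are collapsed and 0.80 is added to
#' probe the low-accuracy regime.
#'
#' @param target_dice numeric Dice targets; `NA` (or the "ground_truth"
#'   label) denotes the unperturbed ground-truth level.
#' @param mode perturbation mode for degraded levels.
#' @param fu1_dice_offset additive Dice offset for first-follow-up masks
#'   (follow-up segmentations are slightly less accurate; default -0.02).
#' @return data frame of class `quality_levels`.
#' @export
quality_levels <- function(target_dice = c(NA, 0.90, 0.88, 0.85, 0.80),
                           mode = "deformation", fu1_dice_offset = -0.02) {
  lab <- ifelse(is.na(target_dice), "ground_truth",
                sprintf("dice_%.2f", target_dice))
  structure(data.frame(label = lab, target_dice = target_dice,
                       mode = mode, fu1_dice_offset = fu1_dice_offset,
                       stringsAsFactors = FALSE),
            class = c("quality_levels", "data.frame"))
}

#' Run the full segmentation-robustness experiment
#'
#' Paired design over one synthetic cohort: for every quality level the
#' same volumes and split are used and only the lesion masks differ
#' (ground truth, or ground truth degraded to the level's Dice target).
#' Each level runs the complete pipeline: mask degradation, 3436-feature
#' extraction at both timepoints, delta features, mRMR selection on the
#' training split, class-weighted RBF-SVM training, test-set evaluation,
#' and log-rank survival stratification of the test patients.
#'
#' @param config a [cohort_config()].
#' @param levels a [quality_levels()] data frame.
#' @param extraction an [extraction_config()].
#' @param k_features number of mRMR-selected features (default 7).
#' @param svm an [svm_params()].
#' @param seed integer seed controlling cohort generation and mask
#'   perturbation.
#' @param progress print per-level progress.
#' @return object of class `robustness_report`.
#' @export
run_experiment <- function(config = cohort_config(),
                           levels = quality_levels(),
                           extraction = extraction_config(),
                           k_features = 7,
                           svm = svm_params(),
                           seed = 1L,
                           progress = FALSE) {
  config$seed <- as.integer(seed)
  cohort <- generate_cohort(config)
  lesions <- cohort$lesions
  split_of <- stats::setNames(cohort$split$split, cohort$split$patient_id)
  lesions$split <- split_of[lesions$patient_id]
  n_lv <- nrow(levels)

  # per-lesion extraction across all levels, one stack at a time (the
  # stack is mask-independent, so each level reuses it)
  delta_by_level <- vector("list", n_lv)
  dice_by_level <- vector("list", n_lv)
  for (li in seq_len(nrow(lesions))) {
    lid <- lesions$lesion_id[li]
    pid <- lesions$patient_id[li]
    fvs <- vector("list", n_lv)
    dsc <- matrix(NA_real_, n_lv, 2)
    for (tp_i in 1:2) {
      tp <- c("BL", "FU1")[tp_i]
      study <- cohort$studies[[paste(pid, tp, sep = "_")]]
      stack <- build_image_stack(study, lid, extraction)
      gt <- study$gt_masks[[lid]]
      for (lv in seq_len(n_lv)) {
        if (is.na(levels$target_dice[lv])) {
          mask <- gt
          dsc[lv, tp_i] <- 1
        } else {
          tgt <- levels$target_dice[lv] +
            if (tp == "FU1") levels$fu1_dice_offset[lv] else 0
          tgt <- min(max(tgt, 0.05), 1)
          mask <- perturb_to_target_dice(
            gt, tgt, mode = levels$mode[lv],
            seed = child_seed(seed, "perturb", levels$label[lv], lid, tp))
          dsc[lv, tp_i] <- dice_coefficient(mask, gt)
        }
        fv <- extract_feature_vector(study, lid, mask = mask,
                                     config = extraction, stack = stack)
        fvs[[lv]] <- if (tp == "BL") list(bl = fv) else
          c(fvs[[lv]], list(fu1 = fv))
      }
    }
    for (lv in seq_len(n_lv)) {
      delta_by_level[[lv]][[lid]] <- delta_features(fvs[[lv]]$bl,
                                                    fvs[[lv]]$fu1)
      dice_by_level[[lv]][[lid]] <- dsc[lv, ]
    }
    if (progress && li %% 10 == 0)
      message(sprintf("  lesion %d/%d", li, nrow(lesions)))
  }

  results <- vector("list", n_lv)
  gt_selection <- NULL
  for (lv in seq_len(n_lv)) {
    res <- tryCatch(
      run_level(levels[lv, ], delta_by_level[[lv]], dice_by_level[[lv]],
                lesions, cohort$survival, k_features, svm),
      error = function(e) {
        warning(sprintf("level %s failed: %s", levels$label[lv],
                        conditionMessage(e)))
        NULL
      })
    results[[lv]] <- res
    if (!is.null(res) && levels$label[lv] == "ground_truth")
      gt_selection <- res$selection
    if (progress)
      message(sprintf("level %s done", levels$label[lv]))
  }
  for (lv in seq_len(n_lv))
    if (!is.null(results[[lv]]) && !is.null(gt_selection))
      results[[lv]]$overlap_with_gt <-
        feature_overlap(results[[lv]]$selection, gt_selection)
  names(results) <- levels$label
  structure(list(levels = levels, results = results,
                 lesions = lesions, survival = cohort$survival,
                 split = cohort$split, seed = seed,
                 config = unclass(config)),
            class = "robustness_report")
}

run_level <- function(level, deltas, dices, lesions, survival_records,
                      k_features, svm) {
  X <- do.call(rbind, deltas[lesions$lesion_id])
  rownames(X) <- lesions$lesion_id
  y <- lesions$true_outcome
  train <- lesions$split == "train"
  test <- lesions$split == "test"
  sel <- mrmr_miq_select(X[train, , drop = FALSE], y[train], k = k_features)
  Xs <- X[, sel$names, drop = FALSE]
  norm <- fit_normalizer(Xs[train, , drop = FALSE])
  model <- train_svm(apply_normalizer(norm, Xs[train, , drop = FALSE]),
                     y[train], svm)
  metrics <- evaluate_model(model,
                            apply_normalizer(norm, Xs[test, , drop = FALSE]),
                            y[test])
  preds <- data.frame(lesion_id = lesions$lesion_id[test],
                      predicted = metrics$predictions$label,
                      score = metrics$predictions$score,
                      true = y[test], stringsAsFactors = FALSE)
  test_patients <- unique(lesions$patient_id[test])
  cohorts <- stratify_cohorts(
    data.frame(lesion_id = preds$lesion_id, predicted = preds$predicted,
               stringsAsFactors = FALSE),
    lesions[, c("lesion_id", "patient_id")], test_patients)
  lr <- cohort_logrank(cohorts, survival_records)
  achieved <- do.call(rbind, dices[lesions$lesion_id])
  list(label = level$label,
       target_dice = level$target_dice,
       achieved_dice_mean = mean(achieved, na.rm = TRUE),
       selection = sel,
       metrics = metrics[c("accuracy", "sensitivity", "specificity",
                           "auc", "f1")],
       confusion = metrics$confusion,
       predictions = preds,
       cohorts = cohorts,
       logrank = lr,
       overlap_with_gt = NA_integer_)
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("<robustness_report>\n")
  for (lab in names(x$results)) {
    r <- x$results[[lab]]
    if (is.null(r)) { cat(sprintf("  %s: FAILED\n", lab)); next }
    cat(sprintf(
      "  %-13s dice %.3f  overlap %s/%d  AUC %.3f  acc %.1f%%  logrank p %s\n",
      lab, r$achieved_dice_mean,
      ifelse(is.na(r$overlap_with_gt), "?", r$overlap_with_gt),
      r$selection$k, r$metrics$auc, r$metrics$accuracy,
      if (is.null(r$logrank)) "NA" else format.pval(r$logrank$p_value,
                                                    digits = 3)))
  }
  invisible(x)
}

#' Serialize a robustness report to JSON and CSV tables
#'
#' Writes `report.json` (full machine-readable report), `quality.csv`
#' (achieved Dice per level), `features.csv` (selected features per level
#' with a boolean `shared_with_ground_truth` column), and `metrics.csv`
#' (columns Accuracy, Sensitivity, Specificity, AUC, F1 per level, plus
#' the log-rank statistic and p-value).
#'
#' @param report a `robustness_report`.
#' @param path output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_report <- function(report, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  gt_names <- NULL
  if (!is.null(report$results$ground_truth))
    gt_names <- report$results$ground_truth$selection$names
  rows_f <- list(); rows_m <- list(); rows_q <- list()
  for (lab in names(report$results)) {
    r <- report$results[[lab]]
    if (is.null(r)) next
    rows_q[[lab]] <- data.frame(level = lab, target_dice = r$target_dice,
                                achieved_dice_mean = r$achieved_dice_mean)
    rows_f[[lab]] <- data.frame(
      level = lab, rank = seq_along(r$selection$names),
      feature = r$selection$names,
      shared_with_ground_truth = r$selection$names %in% gt_names)
    rows_m[[lab]] <- data.frame(
      Level = lab, Accuracy = r$metrics$accuracy,
      Sensitivity = r$metrics$sensitivity,
      Specificity = r$metrics$specificity,
      AUC = r$metrics$auc, F1 = r$metrics$f1,
      LogRankStatistic = if (is.null(r$logrank)) NA else
        r$logrank$statistic,
      LogRankP = if (is.null(r$logrank)) NA else r$logrank$p_value,
      OverlapWithGroundTruth = r$overlap_with_gt)
  }
  files <- c(file.path(path, "report.json"), file.path(path, "quality.csv"),
             file.path(path, "features.csv"), file.path(path, "metrics.csv"))
  json <- report
  json$results <- lapply(report$results, function(r) {
    if (is.null(r)) return(NULL)
    r$selection <- r$selection[c("names", "relevance", "redundancy",
                                 "score", "k")]
    r$logrank <- if (is.null(r$logrank)) NULL else
      r$logrank[c("statistic", "p_value")]
    r
  })
  jsonlite::write_json(json, files[1], auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  write.csv(do.call(rbind, rows_q), files[2], row.names = FALSE)
  write.csv(do.call(rbind, rows_f), files[3], row.names = FALSE)
  write.csv(do.call(rbind, rows_m), files[4], row.names = FALSE)
  invisible(files)
}

#' Read back a serialized robustness report
#'
#' @param path directory written by [write_report()].
#' @return list with the parsed JSON report and the three CSV tables.
#' @export
read_report <- function(path) {
  list(report = jsonlite::read_json(file.path(path, "report.json"),
                                    simplifyVector = TRUE),
       quality = read.csv(file.path(path, "quality.csv")),
       features = read.csv(file.path(path, "features.csv")),
       metrics = read.csv(file.path(path, "metrics.csv")))
}
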