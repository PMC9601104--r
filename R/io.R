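# Plain-text I/O: cohort manifests and survival tables as CSV, feature
# tables as CSV (rows = lesions, columns = feature names), configurations
# as YAML. Volumes stay in memory; no binary image format is written.

#' Write the cohort manifest and survival records
#'
#' `manifest.csv` has one row per lesion (patient_id, lesion_id, split,
#' outcome, volumes); `survival.csv` one row per patient (patient_id,
#' pfs_time, event).
#'
#' @param cohort a `synthetic_cohort`.
#' @param path output directory.
#' @return invisibly, the written paths.
#' @export
write_cohort_tables <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  split_of <- stats::setNames(cohort$split$split, cohort$split$patient_id)
  manifest <- data.frame(
    patient_id = cohort$lesions$patient_id,
    lesion_id = cohort$lesions$lesion_id,
    split = split_of[cohort$lesions$patient_id],
    outcome = cohort$lesions$true_outcome,
    bl_volume_cc = cohort$lesions$bl_volume_cc,
    fu1_volume_cc = cohort$lesions$fu1_volume_cc)
  f1 <- file.path(path, "manifest.csv")
  f2 <- file.path(path, "survival.csv")
  write.csv(manifest, f1, row.names = FALSE)
  write.csv(cohort$survival, f2, row.names = FALSE)
  invisible(c(f1, f2))
}

#' Write / read a cohort configuration as YAML
#'
#' @param config a [cohort_config()].
#' @param path YAML file path.
#' @export
write_cohort_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  do.call(cohort_config, yaml::read_yaml(path))
}

#' Write a feature table (lesions x features) as CSV
#'
#' @param features numeric matrix with lesion ids as row names and
#'   feature names as columns.
#' @param path CSV file path.
#' @export
write_feature_table <- function(features, path) {
  df <- data.frame(lesion_id = rownames(features), features,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
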