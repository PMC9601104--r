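#' Kaplan-Meier product-limit estimate
#'
#' Censored subjects leave the risk set after their time; at tied times
#' events are processed before censorings (the standard convention).
#'
#' @param times positive event/censoring times.
#' @param events 1 = event, 0 = censored.
#' @return object of class `km_curve`: data frame with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (one row per distinct time).
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  stopifnot(length(times) == length(events), all(times > 0))
  events <- as.integer(events)
  ut <- sort(unique(times))
  n <- length(times)
  out <- data.frame(time = ut, n_risk = NA_real_, n_event = NA_real_,
                    n_censor = NA_real_, surv = NA_real_)
  s <- 1
  for (r in seq_along(ut)) {
    t0 <- ut[r]
    at_risk <- sum(times >= t0)
    d <- sum(times == t0 & events == 1)
    c0 <- sum(times == t0 & events == 0)
    if (at_risk > 0 && d > 0) s <- s * (1 - d / at_risk)
    out[r, ] <- list(t0, at_risk, d, c0, s)
  }
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard O-E over hypergeometric variance chi-square with 1 degree of
#' freedom; p-value from the upper tail.
#'
#' @param times positive times.
#' @param events 1 = event, 0 = censored.
#' @param groups two-level group labels.
#' @return list of class `logrank_result` with `statistic`, `p_value`,
#'   `observed`, `expected` (per group).
#' @export
logrank_test <- function(times, events, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("log-rank test needs exactly two groups")
  events <- as.integer(events)
  g1 <- levels(groups)[1]
  ut <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t0 in ut) {
    n_tot <- sum(times >= t0)
    n_1 <- sum(times >= t0 & groups == g1)
    d_tot <- sum(times == t0 & events == 1)
    d_1 <- sum(times == t0 & events == 1 & groups == g1)
    o1 <- o1 + d_1
    e1 <- e1 + d_tot * n_1 / n_tot
    if (n_tot > 1)
      v <- v + d_tot * (n_1 / n_tot) * (1 - n_1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  obs <- c(o1, sum(events == 1) - o1)
  expd <- c(e1, sum(events == 1) - e1)
  names(obs) <- names(expd) <- levels(groups)
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 observed = obs, expected = expd),
            class = "logrank_result")
}

#' Stratify test patients by predicted lesion outcome
#'
#' Cohort 2 contains the test patients with at least one lesion whose
#' predicted outcome is local failure; cohort 1 contains all other test
#' patients. The two cohorts partition the test patients.
#'
#' @param predictions data frame with `lesion_id` and `predicted` label.
#' @param lesion_map data frame with `lesion_id` and `patient_id`.
#' @param test_patients character vector of test-set patient ids.
#' @return list with `cohort1` and `cohort2` (character vectors).
#' @export
stratify_cohorts <- function(predictions, lesion_map, test_patients) {
  m <- merge(predictions, lesion_map, by = "lesion_id")
  if (nrow(m) < nrow(predictions))
    stop("unmapped lesion(s) in predictions")
  lf_pat <- unique(m$patient_id[m$predicted == "LF"])
  cohort2 <- intersect(test_patients, lf_pat)
  list(cohort1 = setdiff(test_patients, cohort2), cohort2 = cohort2)
}

#' Log-rank comparison of prediction-stratified cohorts
#'
#' @param cohorts output of [stratify_cohorts()].
#' @param survival_records data frame with `patient_id`, `pfs_time`,
#'   `event`.
#' @return a `logrank_result`, or `NULL` when either cohort is empty.
#' @export
cohort_logrank <- function(cohorts, survival_records) {
  if (length(cohorts$cohort1) == 0 || length(cohorts$cohort2) == 0)
    return(NULL)
  sel <- survival_records$patient_id %in% c(cohorts$cohort1, cohorts$cohort2)
  sr <- survival_records[sel, ]
  grp <- ifelse(sr$patient_id %in% cohorts$cohort2, "cohort2", "cohort1")
  logrank_test(sr$pfs_time, sr$event, grp)
}
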