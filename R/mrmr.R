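#' One-way ANOVA F statistic between two classes
#'
#' Relevance measure for feature selection: the F statistic of the
#' between-class to within-class variance ratio (1 and n-2 degrees of
#' freedom for two classes).
#'
#' @param values numeric per-sample feature values.
#' @param labels two-level factor/character vector.
#' @return scalar F value.
#' @export
f_statistic <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("both classes must be present")
  if (any(table(labels) < 2)) stop("need at least 2 samples per class")
  drop(col_f_statistics(matrix(values, ncol = 1), labels))
}

# vectorized F over feature columns
col_f_statistics <- function(X, labels) {
  labels <- droplevels(as.factor(labels))
  n <- nrow(X)
  g <- nlevels(labels)
  gm <- colMeans(X)
  ss_between <- 0
  ss_within <- 0
  for (lv in levels(labels)) {
    sel <- labels == lv
    m <- colMeans(X[sel, , drop = FALSE])
    ss_between <- ss_between + sum(sel) * (m - gm)^2
    ss_within <- ss_within +
      colSums(sweep(X[sel, , drop = FALSE], 2, m)^2)
  }
  ms_between <- ss_between / (g - 1)
  ms_within <- ss_within / (n - g)
  f <- ifelse(ms_within > 0, ms_between / ms_within,
              ifelse(ms_between > 0, Inf, 0))
  as.numeric(f)
}

#' Greedy mRMR feature selection with the quotient criterion
#'
#' Minimum-redundancy maximum-relevance forward selection: relevance is
#' the class F statistic, redundancy the mean absolute Pearson correlation
#' with the already-selected set, and each step picks the candidate
#' maximizing their quotient. The first pick maximizes relevance alone.
#' Constant feature columns are dropped with a warning; ties break by
#' column order, so the result is deterministic given the input order.
#'
#' @param features numeric matrix (samples x features) with column names.
#' @param labels two-level class vector, one per row.
#' @param k number of features to select (default 7).
#' @param redundancy_floor lower bound on mean redundancy, guarding the
#'   quotient when a candidate is uncorrelated with all selected features.
#' @return object of class `mrmr_selection`: list with `names`,
#'   `relevance`, `redundancy`, `score` (all in selection order).
#' @export
mrmr_miq_select <- function(features, labels, k = 7,
                            redundancy_floor = 1e-6) {
  stopifnot(is.matrix(features), !is.null(colnames(features)))
  keep <- apply(features, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning(sprintf("dropping %d constant feature column(s)", sum(!keep)))
    features <- features[, keep, drop = FALSE]
  }
  p <- ncol(features)
  if (k > p) stop("k exceeds the number of usable features")
  relevance <- col_f_statistics(features, labels)
  sel <- integer(0)
  rel_out <- red_out <- score_out <- numeric(0)
  # centred/scaled columns make incremental Pearson a crossproduct
  Z <- scale(features)
  n1 <- nrow(features) - 1
  abs_cor_sum <- numeric(p)
  for (step in seq_len(k)) {
    if (step == 1) {
      red <- rep(NA_real_, p)
      score <- relevance
    } else {
      red <- pmax(abs_cor_sum / length(sel), redundancy_floor)
      score <- relevance / red
    }
    score[sel] <- -Inf
    pick <- which.max(score)
    sel <- c(sel, pick)
    rel_out <- c(rel_out, relevance[pick])
    red_out <- c(red_out, red[pick])
    score_out <- c(score_out, score[pick])
    abs_cor_sum <- abs_cor_sum + abs(drop(crossprod(Z, Z[, pick])) / n1)
  }
  structure(list(names = colnames(features)[sel], relevance = rel_out,
                 redundancy = red_out, score = score_out, k = k),
            class = "mrmr_selection")
}

#' @export
print.mrmr_selection <- function(x, ...) {
  cat(sprintf("<mrmr_selection> k = %d\n", x$k))
  for (i in seq_along(x$names))
    cat(sprintf("  %d. %s (F = %.3g%s)\n", i, x$names[i], x$relevance[i],
                if (is.na(x$redundancy[i])) "" else
                  sprintf(", redundancy = %.3g", x$redundancy[i])))
  invisible(x)
}

#' Number of features shared by two selections
#'
#' Order-insensitive intersection size of the selected name sets.
#'
#' @param a,b `mrmr_selection` objects or character vectors of names.
#' @return integer overlap count.
#' @export
feature_overlap <- function(a, b) {
  na <- if (inherits(a, "mrmr_selection")) a$names else a
  nb <- if (inherits(b, "mrmr_selection")) b$names else b
  length(intersect(na, nb))
}
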