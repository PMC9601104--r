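#' SVM hyperparameters
#'
#' Defaults: penalty `C = 1`, `gamma = 1/num_features` (recomputed from
#' the selected feature count when `NULL`), KKT tolerance `1e-3`, class
#' weights inversely proportional to class frequencies.
#'
#' @param C soft-margin penalty.
#' @param gamma RBF kernel width; `NULL` means `1 / ncol(features)`.
#' @param tol support-vector / KKT threshold.
#' @param class_weight "balanced" (inverse frequency) or a named numeric
#'   vector of per-class weights.
#' @return list of class `svm_params`.
#' @export
svm_params <- function(C = 1, gamma = NULL, tol = 1e-3,
                       class_weight = "balanced") {
  stopifnot(C > 0, is.null(gamma) || gamma > 0, tol > 0)
  structure(list(C = C, gamma = gamma, tol = tol,
                 class_weight = class_weight),
            class = "svm_params")
}

#' Fit a train-set min-max normalizer
#'
#' Per-feature min-max coefficients computed on the training set only;
#' applying them to other data may produce values outside `[0, 1]`
#' (no clipping), which is the documented leakage-free contract.
#'
#' @param train numeric matrix (samples x features) with column names.
#' @return list of class `minmax_normalizer`.
#' @export
fit_normalizer <- function(train) {
  stopifnot(is.matrix(train))
  mins <- apply(train, 2, min)
  maxs <- apply(train, 2, max)
  bad <- maxs - mins <= 0
  if (any(bad))
    stop("constant training feature(s): ",
         paste(colnames(train)[bad], collapse = ", "))
  structure(list(min = mins, max = maxs), class = "minmax_normalizer")
}

#' @rdname fit_normalizer
#' @param normalizer a fitted normalizer.
#' @param features matrix to transform (same columns as the training set).
#' @export
apply_normalizer <- function(normalizer, features) {
  stopifnot(inherits(normalizer, "minmax_normalizer"))
  sweep(sweep(features, 2, normalizer$min), 2,
        normalizer$max - normalizer$min, `/`)
}

svm_class_weights <- function(labels, class_weight) {
  tab <- table(labels)
  if (identical(class_weight, "balanced"))
    stats::setNames(as.numeric(sum(tab) / (length(tab) * tab)), names(tab))
  else {
    stopifnot(all(names(tab) %in% names(class_weight)))
    class_weight[names(tab)]
  }
}

#' Train a class-weighted Gaussian-kernel SVM
#'
#' Solves the dual soft-margin problem exactly (quadratic programming)
#' with per-class box constraints `C_i = C * w_class`, Gaussian kernel
#' `exp(-gamma * ||x - y||^2)`. The positive class is "LF" (local
#' failure); the decision score is the usual signed distance surrogate
#' `sum(alpha_i y_i K(x_i, x)) + b`.
#'
#' @param features numeric matrix (samples x features), typically already
#'   min-max normalized with [fit_normalizer()].
#' @param labels vector with levels "LC"/"LF" (both present).
#' @param params an [svm_params()].
#' @return object of class `rbf_svm`.
#' @export
train_svm <- function(features, labels, params = svm_params()) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2) stop("need exactly two classes")
  lev <- levels(droplevels(labels))
  pos <- if ("LF" %in% lev) "LF" else lev[2]
  y <- ifelse(labels == pos, 1, -1)
  n <- nrow(features)
  gamma <- if (is.null(params$gamma)) 1 / ncol(features) else params$gamma
  w <- svm_class_weights(labels, params$class_weight)
  Ci <- params$C * as.numeric(w[as.character(labels)])
  K <- rbf_kernel(features, features, gamma)
  Q <- (y %o% y) * K
  ridge <- 1e-8
  sol <- quadprog::solve.QP(
    Dmat = Q + diag(ridge, n),
    dvec = rep(1, n),
    Amat = cbind(y, diag(n), -diag(n)),
    bvec = c(0, rep(0, n), -Ci),
    meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), Ci)
  sv <- alpha > params$tol * max(alpha)
  free <- sv & alpha < Ci - params$tol * max(Ci)
  ref <- if (any(free)) free else sv
  b <- mean(y[ref] - drop(K[ref, sv, drop = FALSE] %*% (alpha[sv] * y[sv])))
  structure(list(sv_x = features[sv, , drop = FALSE],
                 sv_coef = alpha[sv] * y[sv],
                 b = b, gamma = gamma, positive = pos,
                 levels = lev, params = params),
            class = "rbf_svm")
}

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Decision scores and hard labels for new samples
#'
#' @param object a fitted `rbf_svm`.
#' @param newdata feature matrix on the training columns.
#' @param ... unused.
#' @return data frame with `score` (continuous) and `label` (positive
#'   class when score >= 0).
#' @export
predict.rbf_svm <- function(object, newdata, ...) {
  K <- rbf_kernel(as.matrix(newdata), object$sv_x, object$gamma)
  score <- drop(K %*% object$sv_coef) + object$b
  neg <- setdiff(object$levels, object$positive)
  data.frame(score = score,
             label = ifelse(score >= 0, object$positive, neg),
             stringsAsFactors = FALSE)
}

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' Ties contribute 1/2.
#'
#' @param scores continuous decision scores.
#' @param labels class vector; `positive` is the event class.
#' @param positive positive-class label.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels, positive = "LF") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  if (length(pos) == 0 || length(neg) == 0)
    stop("AUC undefined: need both classes")
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Classification metric report
#'
#' Accuracy, sensitivity, specificity and F1 (percent) from the confusion
#' matrix with local failure (LF) as the positive class, plus the rank
#' AUC of the continuous scores.
#'
#' @param model fitted `rbf_svm`.
#' @param features test feature matrix (already normalized consistently
#'   with training).
#' @param labels true test labels.
#' @return list of class `metric_report` with `accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `f1`, and the `confusion` table.
#' @export
evaluate_model <- function(model, features, labels) {
  stopifnot(nrow(features) > 0)
  pred <- predict(model, features)
  pos <- model$positive
  tp <- sum(pred$label == pos & labels == pos)
  fn <- sum(pred$label != pos & labels == pos)
  tn <- sum(pred$label != pos & labels != pos)
  fp <- sum(pred$label == pos & labels != pos)
  auc <- if (length(unique(labels)) == 2)
    auc_mann_whitney(pred$score, labels, pos) else NA_real_
  structure(list(
    accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    auc = auc,
    f1 = if (2 * tp + fp + fn > 0) 100 * 2 * tp / (2 * tp + fp + fn)
         else NA_real_,
    confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
    predictions = pred),
    class = "metric_report")
}

#' Confusion-matrix metrics without a model
#'
#' Convenience constructor used by reports and tests: metrics from raw
#' confusion counts (LF positive).
#'
#' @param tp,fn,tn,fp confusion counts.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `f1` in
#'   percent.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  list(accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       f1 = 100 * 2 * tp / (2 * tp + fp + fn))
}
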