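# Stratified cross-validation, confusion metrics, ROC/PRC curves.

#' Stratified k-fold assignments
#'
#' Partitions record indices into k disjoint test folds such that each fold's
#' class counts are within one record of proportional. Deterministic given
#' `seed`.
#'
#' @param labels Factor or character vector of binary labels.
#' @param k Number of folds (default 5, i.e. 80/20 train/test splits).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per record.
#' @export
#' @examples
#' table(stratified_kfold(rep(c("absent", "present"), c(70, 30)), seed = 1))
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (n < k) stop("fewer records than folds")
  if (nlevels(droplevels(labels)) < 2L) stop("both classes must be present")
  cnt <- table(droplevels(labels))
  if (any(cnt < k)) {
    stop("class '", names(cnt)[which.min(cnt)], "' has fewer records (",
         min(cnt), ") than folds (", k, ")")
  }
  set.seed(seed)
  fold <- integer(n)
  for (lv in levels(droplevels(labels))) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Confusion counts
#'
#' TP counts correctly classified tremor-present records, TN correctly
#' classified tremor-absent records, FP misclassified absent records, FN
#' misclassified present records.
#'
#' @param truth,pred Binary label vectors (`"present"`/`"absent"`) of equal
#'   length.
#' @param positive The positive class label.
#' @return Named list `TP`, `FP`, `TN`, `FN` of class `"confusion_counts"`.
#' @export
confusion_counts <- function(truth, pred, positive = "present") {
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  truth_pos <- as.character(truth) == positive
  pred_pos <- as.character(pred) == positive
  structure(list(TP = sum(truth_pos & pred_pos),
                 FP = sum(!truth_pos & pred_pos),
                 TN = sum(!truth_pos & !pred_pos),
                 FN = sum(truth_pos & !pred_pos)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall, specificity and F1. Specificity is computed
#' as the standard TN / (TN + FP); `specificity_as_printed = TRUE`
#' reproduces, for audit, the variant TN / (TN + FN) that appears in some
#' write-ups. Undefined ratios (0/0) return 0 with a warning.
#'
#' @param counts A [confusion_counts()] object or list with TP/FP/TN/FN.
#' @param specificity_as_printed Use TN / (TN + FN) instead of the standard
#'   definition.
#' @return Named list `accuracy`, `precision`, `recall`, `specificity`,
#'   `f1`, all in \[0, 1\].
#' @export
compute_metrics <- function(counts, specificity_as_printed = FALSE) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion counts")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("0/0 in ", what, "; returning 0")
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  spec_den <- if (specificity_as_printed) tn + fn else tn + fp
  specificity <- safe_div(tn, spec_den, "specificity")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / total, precision = precision, recall = recall,
       specificity = specificity, f1 = f1)
}

#' ROC and precision-recall curves
#'
#' Sweeps the decision threshold over the unique scores, computing ROC
#' points (FPR, TPR) and PRC points (recall, precision). AUROC is the
#' trapezoidal area; AUPRC uses step interpolation (average precision),
#' which does not overstate precision between operating points.
#'
#' @param scores Positive-class scores in \[0, 1\].
#' @param truth Binary labels; both classes must be present.
#' @param positive Positive class label.
#' @return List `roc` (data frame threshold/fpr/tpr), `prc` (data frame
#'   threshold/recall/precision), `auroc`, `auprc`.
#' @export
roc_pr_curves <- function(scores, truth, positive = "present") {
  truth_pos <- as.character(truth) == positive
  np <- sum(truth_pos)
  nn <- sum(!truth_pos)
  if (np == 0 || nn == 0) stop("both classes must be present in `truth`")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth_pos[ord]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- c(diff(s) != 0, TRUE) # take the last index of each tied score
  thr <- s[last]
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  recall <- tp[last] / np
  precision <- tp[last] / (tp[last] + fp[last])
  auprc <- sum(diff(c(0, recall)) * precision)
  list(roc = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
       prc = data.frame(threshold = thr, recall = recall,
                        precision = precision),
       auroc = auroc, auprc = auprc)
}

#' Cross-validate a tremor detection pipeline
#'
#' Stratified k-fold cross-validation: features are extracted once, the
#' pipeline is fitted on each training fold (a no-op for the rule
#' pipelines, which have no trainable parameters) and evaluated on the
#' held-out fold. ROC/PRC curves are accumulated for score-producing
#' pipelines (`b1`, `b2` by default; the engineered-feature pipelines are
#' reported as single operating points) along with fold-averaged curves on
#' a common grid.
#'
#' @param data A `"tremor_dataset"` or labeled feature data frame.
#' @param pipeline Pipeline id, see [tremor_fit()].
#' @param k Folds (default 5).
#' @param seed Integer seed for fold assignment and per-fold fits.
#' @param control,kernel Passed to [tremor_fit()].
#' @param features Optional precomputed [tremor_features()] table (saves
#'   recomputation when several pipelines share one family).
#' @param curves Collect ROC/PRC curves; default `TRUE` for `b1`/`b2`.
#' @param specificity_as_printed See [compute_metrics()].
#' @return An object of class `"tremor_cv"`: per-fold metrics, mean/sd
#'   summary, and optional curves.
#' @export
cross_validate <- function(data, pipeline, k = 5L, seed = 1L, control = NULL,
                           kernel = c("radial", "linear"), features = NULL,
                           curves = tolower(pipeline) %in% c("b1", "b2"),
                           specificity_as_printed = FALSE) {
  pipeline <- match.arg(tolower(pipeline), PIPELINES)
  kernel <- match.arg(kernel)
  if (is.null(features)) {
    features <- if (is.data.frame(data)) data
                else tremor_features(data, feature_family(pipeline),
                                     control = control)
  }
  if (!"label" %in% names(features) || anyNA(features$label)) {
    stop("cross-validation needs labeled data")
  }
  fold <- stratified_kfold(features$label, k = k, seed = seed)
  metric_names <- c("f1", "accuracy", "precision", "recall", "specificity")
  per_fold <- vector("list", k)
  fold_curves <- if (curves) vector("list", k) else NULL
  for (f in seq_len(k)) {
    train <- features[fold != f, , drop = FALSE]
    test <- features[fold == f, , drop = FALSE]
    fit <- tremor_fit(train, pipeline, control = control, kernel = kernel,
                      seed = seed + f)
    score <- predict(fit, test, type = "prob")
    pred <- factor(ifelse(score >= fit$threshold, "present", "absent"),
                   levels = c("absent", "present"))
    m <- compute_metrics(confusion_counts(test$label, pred),
                         specificity_as_printed = specificity_as_printed)
    row <- data.frame(fold = f, n_test = nrow(test), as.data.frame(m))
    if (curves) {
      cv <- roc_pr_curves(score, test$label)
      row$auroc <- cv$auroc
      row$auprc <- cv$auprc
      fold_curves[[f]] <- cv
    }
    per_fold[[f]] <- row
  }
  folds <- do.call(rbind, per_fold)
  cols <- c(metric_names, if (curves) c("auroc", "auprc"))
  summ <- data.frame(metric = cols,
                     mean = vapply(cols, function(cn) mean(folds[[cn]]), 0),
                     sd = vapply(cols, function(cn) sd(folds[[cn]]), 0))
  out <- structure(
    list(pipeline = pipeline, k = k, seed = seed, folds = folds,
         summary = summ, curves = fold_curves),
    class = "tremor_cv")
  if (curves) out$mean_curves <- average_curves(fold_curves)
  out
}

# Vertical curve averaging on common grids (101 points).
average_curves <- function(fold_curves) {
  grid <- seq(0, 1, length.out = 101L)
  tprs <- vapply(fold_curves, function(cv) {
    approx(cv$roc$fpr, cv$roc$tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(101L))
  precs <- vapply(fold_curves, function(cv) {
    approx(c(0, cv$prc$recall), c(cv$prc$precision[1L], cv$prc$precision),
           xout = grid, ties = min, rule = 2)$y
  }, numeric(101L))
  list(roc = data.frame(fpr = grid, tpr = rowMeans(tprs),
                        tpr_sd = apply(tprs, 1L, sd)),
       prc = data.frame(recall = grid, precision = rowMeans(precs),
                        precision_sd = apply(precs, 1L, sd)))
}

#' @export
print.tremor_cv <- function(x, digits = 3L, ...) {
  cat("<tremor_cv> pipeline ", toupper(x$pipeline), ", ", x$k,
      "-fold stratified CV (seed ", x$seed, ")\n", sep = "")
  s <- x$summary
  cat(paste(sprintf("  %-12s %s (%s)", s$metric,
                    format(round(s$mean, digits), nsmall = 2L),
                    format(round(s$sd, digits), nsmall = 2L)),
            collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.tremor_cv <- function(object, ...) {
  print(object)
  cat("Per-fold metrics:\n")
  print(object$folds, row.names = FALSE, digits = 3L)
  invisible(object)
}

#' Plot averaged ROC and precision-recall curves
#'
#' Fold-averaged curves with a +/- 1 SD band; available for
#' cross-validations that collected scores (`b1`, `b2` by default).
#'
#' @param x A `"tremor_cv"` with curves.
#' @param ... Unused.
#' @export
plot.tremor_cv <- function(x, ...) {
  if (is.null(x$mean_curves)) {
    stop("no curves collected for pipeline ", toupper(x$pipeline),
         " (rule pipelines are single operating points)")
  }
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  band <- function(xx, m, s, col) {
    polygon(c(xx, rev(xx)), c(pmin(m + s, 1), rev(pmax(m - s, 0))),
            col = adjustcolor(col, 0.25), border = NA)
  }
  r <- x$mean_curves$roc
  plot(r$fpr, r$tpr, type = "n", xlab = "False positive rate",
       ylab = "True positive rate",
       main = paste0("ROC (", toupper(x$pipeline), ")"))
  band(r$fpr, r$tpr, r$tpr_sd, "steelblue")
  lines(r$fpr, r$tpr, col = "steelblue", lwd = 2)
  abline(0, 1, lty = 3)
  p <- x$mean_curves$prc
  plot(p$recall, p$precision, type = "n", ylim = c(0, 1), xlab = "Recall",
       ylab = "Precision",
       main = paste0("PRC (", toupper(x$pipeline), ")"))
  band(p$recall, p$precision, p$precision_sd, "firebrick")
  lines(p$recall, p$precision, col = "firebrick", lwd = 2)
  invisible(x)
}
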