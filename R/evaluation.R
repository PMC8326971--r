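# Confusion-matrix algebra, the seven guideline measures, ROC/PR curves.
#
# The seven measures (accuracy, precision/PPV, recall/sensitivity,
# specificity, F1, NPV, MCC) follow the Human Mutation guideline formulas for
# a binary classifier. Zero-denominator cases yield NA with the affected
# measure recorded in `undefined`, never silent NaN.

#' Construct a confusion matrix
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("confusion-matrix counts must be non-negative")
  if (any(counts != round(counts))) stop("confusion-matrix counts must be integers")
  if (sum(counts) < 1) stop("confusion matrix must contain at least one observation")
  structure(as.list(stats::setNames(as.integer(counts), names(counts))),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L,
              dimnames = list(predicted = c("positive", "negative"),
                              actual = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Confusion matrix from probabilistic predictions
#'
#' The positive class is "splicing-pathogenic"; a probability of exactly the
#' threshold counts as a predicted positive (0.5 or more means
#' splicing-affecting).
#'
#' @param labels Binary vector (1 = pathogenic, 0 = common).
#' @param probabilities Predicted probabilities in `[0, 1]`.
#' @param threshold Decision threshold, default 0.5.
#' @return A `confusion_matrix`.
#' @export
confusion_from_predictions <- function(labels, probabilities, threshold = 0.5) {
  if (length(labels) != length(probabilities)) {
    stop("labels (", length(labels), ") and probabilities (",
         length(probabilities), ") differ in length")
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pred <- probabilities >= threshold
  confusion_matrix(tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
                   fn = sum(!pred & labels == 1), tn = sum(!pred & labels == 0))
}

#' The seven guideline measures of a confusion matrix
#'
#' accuracy = (TP+TN)/total; precision = TP/(TP+FP);
#' recall = TP/(TP+FN); specificity = TN/(FP+TN);
#' F1 = 2*precision*recall/(precision+recall); NPV = TN/(TN+FN);
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#'
#' @param cm A `confusion_matrix`.
#' @return A `metrics_report`: list of the seven measures (NA where a
#'   denominator is zero) plus `confusion` and `undefined`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  fn <- as.numeric(cm$fn); tn <- as.numeric(cm$tn)
  total <- tp + fp + fn + tn
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  mcc_den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  rep <- list(accuracy = safe(tp + tn, total),
              precision = precision,
              recall = recall,
              specificity = safe(tn, fp + tn),
              f1 = f1,
              npv = safe(tn, tn + fn),
              mcc = mcc)
  structure(c(rep, list(confusion = cm,
                        undefined = names(rep)[vapply(rep, is.na, logical(1))])),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3L, ...) {
  v <- unlist(x[METRIC_NAMES])
  cat("seven guideline measures (NA = undefined denominator):\n")
  print(round(v, digits))
  invisible(x)
}

METRIC_NAMES <- c("accuracy", "precision", "recall", "specificity",
                  "f1", "npv", "mcc")

#' Names of the seven guideline measures
#' @return Character vector.
#' @export
metric_names <- function() METRIC_NAMES

#' ROC curve and AUROC
#'
#' Threshold sweep over the unique scores (tied scores grouped), TPR vs FPR,
#' area by the trapezoidal rule. Equivalent to the Mann-Whitney U statistic
#' normalized by the number of positive-negative pairs.
#'
#' @param labels Binary vector (1 = positive).
#' @param probabilities Scores; larger means more positive.
#' @return List with `points` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auroc`.
#' @export
roc_curve <- function(labels, probabilities) {
  if (length(labels) != length(probabilities)) stop("length mismatch")
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) stop("ROC needs both classes present")
  o <- order(probabilities, decreasing = TRUE)
  lab <- labels[o]; pr <- probabilities[o]
  grp <- !duplicated(pr)                       # group tied scores
  tp <- cumsum(lab == 1); fp <- cumsum(lab == 0)
  last_of_group <- c(which(grp[-1L]) , length(pr))  # last index of each tie group
  tpr <- c(0, tp[last_of_group] / P)
  fpr <- c(0, fp[last_of_group] / N)
  thr <- c(Inf, pr[last_of_group])
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
       auroc = auroc)
}

#' Precision-recall curve and AUPR
#'
#' Threshold sweep over unique scores; the area uses right-continuous step
#' integration (sum of precision times recall increments), which avoids the
#' optimism of linear interpolation in PR space.
#'
#' @inheritParams roc_curve
#' @return List with `points` (data.frame `recall`, `precision`, `threshold`)
#'   and `aupr`.
#' @export
pr_curve <- function(labels, probabilities) {
  if (length(labels) != length(probabilities)) stop("length mismatch")
  P <- sum(labels == 1)
  if (P == 0) stop("PR curve needs at least one positive")
  o <- order(probabilities, decreasing = TRUE)
  lab <- labels[o]; pr <- probabilities[o]
  grp <- !duplicated(pr)
  tp <- cumsum(lab == 1); n_pred <- seq_along(lab)
  last_of_group <- c(which(grp[-1L]), length(pr))
  recall <- tp[last_of_group] / P
  precision <- tp[last_of_group] / n_pred[last_of_group]
  aupr <- sum(diff(c(0, recall)) * precision)
  list(points = data.frame(recall = recall, precision = precision,
                           threshold = pr[last_of_group]),
       aupr = aupr)
}

#' Vertically average per-fold curves
#'
#' Interpolates each fold's curve (linearly) onto a fixed 101-point grid of
#' the x axis (FPR for ROC, recall for PR) and reports the pointwise mean and
#' standard deviation across folds.
#'
#' @param curves List of curve objects from [roc_curve()] or [pr_curve()].
#' @param type `"roc"` or `"pr"`.
#' @return List with `grid`, `mean`, `sd` (each length 101) and `type`.
#' @export
mean_curves <- function(curves, type = c("roc", "pr")) {
  type <- match.arg(type)
  if (length(curves) < 2L) stop("need at least 2 fold curves to average")
  grid <- seq(0, 1, length.out = 101L)
  ys <- vapply(curves, function(cv) {
    pts <- cv$points
    if (nrow(pts) < 2L) stop("fold curve has fewer than 2 points")
    if (type == "roc") {
      stats::approx(pts$fpr, pts$tpr, xout = grid, ties = max, rule = 2)$y
    } else {
      o <- order(pts$recall)
      stats::approx(pts$recall[o], pts$precision[o], xout = grid,
                    ties = max, rule = 2)$y
    }
  }, numeric(101L))
  list(grid = grid, mean = rowMeans(ys), sd = apply(ys, 1L, stats::sd),
       type = type)
}

#' Round for reporting (3 decimals, round-half-even)
#' @param x Numeric.
#' @param digits Decimal places, default 3.
#' @return Rounded numeric (R's `round`, which is round-half-even).
#' @export
report_round <- function(x, digits = 3L) round(x, digits)
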