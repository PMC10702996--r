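# Multi-class diagnostic metrics under one-vs-rest reduction: per-class
# confusion counts, the accuracy / sensitivity / specificity / precision /
# F-measure suite, macro (and support-weighted) averaging, and ROC/AUC by
# threshold sweep.

#' Per-class one-vs-rest confusion counts
#'
#' For each class k the counts treat k as positive and every other class as
#' negative, so `tp + fp + tn + fn` equals the number of samples for every
#' class.
#'
#' @param yTrue,yPred integer labels in `0:(nClasses - 1)`, equal length.
#' @param nClasses number of classes (default 3).
#' @return Data frame with columns `class, tp, fp, tn, fn`.
#' @export
confusionCounts <- function(yTrue, yPred, nClasses = 3L) {
  if (length(yTrue) != length(yPred)) {
    stop("pdfusenet: label vectors differ in length", call. = FALSE)
  }
  if (any(!yTrue %in% 0:(nClasses - 1L)) || any(!yPred %in% 0:(nClasses - 1L))) {
    stop("pdfusenet: labels out of range 0..", nClasses - 1L, call. = FALSE)
  }
  out <- lapply(0:(nClasses - 1L), function(k) {
    pos <- yTrue == k
    hat <- yPred == k
    data.frame(class = k,
               tp = sum(pos & hat), fp = sum(!pos & hat),
               tn = sum(!pos & !hat), fn = sum(pos & !hat))
  })
  do.call(rbind, out)
}

safeRatio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Diagnostic metric suite from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, sensitivity (recall) `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)` and the F-measure
#' `2 * precision * recall / (precision + recall)`. A zero denominator
#' yields the sentinel value 0 and the metric's name is recorded in the
#' `"undefined"` attribute. `sensitivityFormula = "printed"` selects the
#' `TP/(TP+FP)` variant instead of the recall definition.
#'
#' @param counts a one-row data frame (or named vector/list) with `tp, fp,
#'   tn, fn`, or the multi-row frame from [confusionCounts()] (metrics are
#'   then computed per row).
#' @param sensitivityFormula `"recall"` (default) or `"printed"`.
#' @return For one row: a named numeric vector with attribute `"undefined"`.
#'   For several rows: a data frame of per-class metrics.
#' @export
metricSuite <- function(counts, sensitivityFormula = c("recall", "printed")) {
  sensitivityFormula <- match.arg(sensitivityFormula)
  if (is.data.frame(counts) && nrow(counts) > 1L) {
    rows <- lapply(seq_len(nrow(counts)), function(i) {
      metricSuite(counts[i, ], sensitivityFormula)
    })
    out <- as.data.frame(do.call(rbind, rows))
    if ("class" %in% names(counts)) out <- cbind(class = counts$class, out)
    return(out)
  }
  counts <- as.list(counts)
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (any(c(tp, fp, tn, fn) < 0)) {
    stop("pdfusenet: confusion counts must be non-negative", call. = FALSE)
  }
  sens <- if (sensitivityFormula == "recall") {
    safeRatio(tp, tp + fn)
  } else {
    safeRatio(tp, tp + fp)
  }
  m <- c(accuracy = safeRatio(tp + tn, tp + fp + tn + fn),
         sensitivity = sens,
         specificity = safeRatio(tn, tn + fp),
         precision = safeRatio(tp, tp + fp))
  recall <- safeRatio(tp, tp + fn)
  f <- if (is.na(recall) || is.na(m[["precision"]]) ||
           (recall + m[["precision"]]) == 0) {
    NA_real_
  } else {
    2 * m[["precision"]] * recall / (m[["precision"]] + recall)
  }
  m <- c(m, fMeasure = f)
  undefined <- names(m)[is.na(m)]
  m[is.na(m)] <- 0
  attr(m, "undefined") <- undefined
  m
}

#' Macro (or support-weighted) average of per-class metrics
#'
#' @param perClass data frame (or matrix) of per-class metric values, one
#'   row per class; a `class` column is ignored.
#' @param weights optional per-class supports for the weighted variant;
#'   `NULL` (default) gives the unweighted macro mean.
#' @return Named numeric vector of averaged metrics.
#' @export
macroAverage <- function(perClass, weights = NULL) {
  if (is.null(dim(perClass)) || nrow(perClass) < 2L) {
    stop("pdfusenet: macro averaging needs >= 2 classes", call. = FALSE)
  }
  df <- as.data.frame(perClass)
  df$class <- NULL
  if (is.null(weights)) weights <- rep(1, nrow(df))
  if (length(weights) != nrow(df)) {
    stop("pdfusenet: one weight per class required", call. = FALSE)
  }
  w <- weights / sum(weights)
  vapply(df, function(col) sum(w * col), numeric(1))
}

#' ROC curve and AUC for binary scores
#'
#' Threshold sweep over the unique scores (ties cross simultaneously), TPR
#' against FPR, AUC by the trapezoid rule — equal, up to tie handling, to
#' the Mann-Whitney pairwise-comparison statistic.
#'
#' @param yTrue binary labels (0/1 or logical); both classes must occur.
#' @param scores numeric scores, larger meaning more positive.
#' @return List with `points` (data frame `threshold, fpr, tpr`) and `auc`.
#' @export
rocAuc <- function(yTrue, scores) {
  yTrue <- as.integer(yTrue)
  if (length(yTrue) != length(scores)) {
    stop("pdfusenet: labels/scores length mismatch", call. = FALSE)
  }
  P <- sum(yTrue == 1L)
  Ng <- sum(yTrue == 0L)
  if (P == 0L || Ng == 0L) {
    stop("pdfusenet: ROC needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- yTrue[ord]
  ss <- scores[ord]
  last <- c(diff(ss) != 0, TRUE)
  tpr <- cumsum(ys)[last] / P
  fpr <- cumsum(1L - ys)[last] / Ng
  points <- data.frame(threshold = c(Inf, ss[last]),
                       fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  list(points = points, auc = auc)
}

#' One-vs-rest ROC curves and macro AUC for a multi-class problem
#'
#' @param yTrue integer labels in `0:(K - 1)`.
#' @param probs N x K row-stochastic score matrix.
#' @return List with `perClass` (AUC per class), `macroAuc` and `curves`
#'   (the per-class ROC point frames).
#' @export
multiclassAuc <- function(yTrue, probs) {
  K <- ncol(probs)
  curves <- vector("list", K)
  aucs <- numeric(K)
  for (k in seq_len(K)) {
    r <- rocAuc(as.integer(yTrue == (k - 1L)), probs[, k])
    curves[[k]] <- r$points
    aucs[k] <- r$auc
  }
  list(perClass = aucs, macroAuc = mean(aucs), curves = curves)
}

#' Full classification report
#'
#' Overall accuracy, per-class one-vs-rest metric suite, macro and
#' support-weighted averages, and (when probabilities are supplied) the
#' macro one-vs-rest AUC.
#'
#' @param yTrue,yPred integer labels.
#' @param probs optional N x K probability matrix for AUC.
#' @param nClasses number of classes.
#' @return List with `overallAccuracy`, `counts`, `perClass`, `macro`,
#'   `weighted` and optionally `auc`.
#' @export
classificationReport <- function(yTrue, yPred, probs = NULL, nClasses = 3L) {
  counts <- confusionCounts(yTrue, yPred, nClasses)
  perClass <- metricSuite(counts)
  support <- vapply(0:(nClasses - 1L), function(k) sum(yTrue == k), numeric(1))
  rep <- list(overallAccuracy = mean(yTrue == yPred),
              counts = counts,
              perClass = perClass,
              macro = macroAverage(perClass),
              weighted = macroAverage(perClass, support))
  if (!is.null(probs)) {
    rep$auc <- multiclassAuc(yTrue, probs)[c("perClass", "macroAuc")]
  }
  rep
}
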