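#' Classifier evaluation report
#'
#' Computes the full agreement report for a set of class-membership scores:
#' confusion matrix (counts and per-true-class percentages), overall
#' accuracy, Cohen's kappa, mean absolute error and root mean squared error
#' over the class scores, and per-class TP rate, FP rate, precision, recall,
#' F-measure, Matthews correlation, ROC area and precision-recall area, plus
#' their support-weighted averages.
#'
#' Definitions: accuracy is `100 * trace / n`; kappa is
#' `(p_o - p_e) / (1 - p_e)` with `p_e` from the marginal products; MAE is
#' the mean over instances and classes of `|score - onehot|` and RMSE the
#' root of the corresponding mean square (the convention of per-class-output
#' error reporting); per-class metrics come from the one-vs-rest 2x2
#' collapse; ROC and PRC areas integrate over the unique score thresholds
#' (trapezoid for ROC, step summation for PRC).
#'
#' @param true_labels True class per instance.
#' @param proba Score matrix (instances x classes) with unit row sums;
#'   column names give the class order if `class_order` is missing.
#' @param class_order Optional explicit class ordering.
#' @return An `evaluation_report` list with elements `confusion_counts`,
#'   `confusion_percent`, `accuracy` (percent), `kappa`, `mae`, `rmse`,
#'   `per_class` (data.frame), `weighted` (named vector) and `n`.
#' @export
evaluate <- function(true_labels, proba, class_order = colnames(proba)) {
  proba <- as.matrix(proba)
  true_labels <- as.character(true_labels)
  stopifnot(length(true_labels) == nrow(proba))
  if (is.null(class_order)) stop("class order required (no column names)")
  if (any(!true_labels %in% class_order))
    stop("true labels outside the class order: ",
         paste(setdiff(unique(true_labels), class_order), collapse = ", "))
  colnames(proba) <- class_order
  n <- nrow(proba)
  k <- length(class_order)
  pred <- class_order[max.col(proba, ties.method = "first")]

  cm <- confusion_counts(true_labels, pred, class_order)
  acc <- 100 * sum(diag(cm)) / n
  kap <- cohen_kappa(cm)

  onehot <- matrix(0, n, k)
  onehot[cbind(seq_len(n), match(true_labels, class_order))] <- 1
  mae <- mean(abs(proba - onehot))
  rmse <- sqrt(mean((proba - onehot)^2))

  per <- do.call(rbind, lapply(seq_len(k), function(j) {
    tp <- cm[j, j]
    fn <- sum(cm[j, ]) - tp
    fp <- sum(cm[, j]) - tp
    tn <- n - tp - fn - fp
    pos <- true_labels == class_order[j]
    data.frame(
      class = class_order[j],
      support = as.integer(tp + fn),
      tp_rate = rate_or(tp, tp + fn, 0),
      fp_rate = rate_or(fp, fp + tn, 0),
      precision = rate_or(tp, tp + fp, 0),
      recall = rate_or(tp, tp + fn, 0),
      f_measure = rate_or(2 * tp, 2 * tp + fp + fn, 0),
      mcc = mcc_counts(tp, fp, tn, fn),
      roc_area = roc_auc(pos, proba[, j]),
      prc_area = prc_auc(pos, proba[, j]),
      stringsAsFactors = FALSE)
  }))
  w <- per$support / sum(per$support)
  weighted <- vapply(per[, !(names(per) %in% c("class", "support"))],
                     function(col) sum(w * col), numeric(1))

  structure(list(confusion_counts = cm,
                 confusion_percent = confusion_percent(cm),
                 accuracy = acc, kappa = kap, mae = mae, rmse = rmse,
                 per_class = per, weighted = weighted, n = n),
            class = "evaluation_report")
}

rate_or <- function(num, den, default) if (den == 0) default else num / den

#' Confusion-matrix counts (true x predicted)
#'
#' @param true_labels,pred_labels Label vectors of equal length.
#' @param class_order Class ordering shared by rows and columns.
#' @return Integer matrix, rows = true class, columns = predicted class.
#' @export
confusion_counts <- function(true_labels, pred_labels,
                             class_order = sort(unique(c(true_labels, pred_labels)))) {
  t_f <- factor(true_labels, levels = class_order)
  p_f <- factor(pred_labels, levels = class_order)
  unclass(table(true = t_f, predicted = p_f))
}

#' Per-true-class percentage layout of a confusion matrix
#'
#' Transposes a true x predicted count matrix into the "classified as"
#' layout: rows are predicted classes, columns are true classes, and every
#' column sums to 100 (a zero-support class yields a zero column, with a
#' warning).
#'
#' @param counts True x predicted count matrix.
#' @return Percentage matrix (predicted x true).
#' @export
confusion_percent <- function(counts) {
  counts <- as.matrix(counts)
  if (!length(counts)) stop("empty confusion matrix")
  support <- rowSums(counts)
  if (any(support == 0)) warning("zero-support class: column left at zero")
  denom <- ifelse(support == 0, 1, support)
  out <- t(sweep(counts, 1, denom, "/") * 100)
  if (!is.null(dimnames(out)))
    names(dimnames(out)) <- c("classified_as", "true")
  out
}

#' Cohen's kappa of a confusion matrix
#'
#' `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o = trace / n` and
#' chance agreement `p_e` from the products of the row and column marginals.
#'
#' @param cm Square count matrix (true x predicted).
#' @return Scalar kappa.
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

mcc_counts <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Area under the ROC curve (one-vs-rest, trapezoidal)
#'
#' Sweeps the unique score thresholds, accumulating the trapezoid area under
#' the (FPR, TPR) curve. Degenerate label vectors (all positive or all
#' negative) return 0.
#'
#' @param positive Logical vector: instance belongs to the class.
#' @param scores Numeric score per instance.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(positive, scores) {
  positive <- as.logical(positive)
  np <- sum(positive)
  nn <- sum(!positive)
  if (np == 0 || nn == 0) return(0)
  ord <- order(scores, decreasing = TRUE)
  pos_sorted <- positive[ord]
  sc <- scores[ord]
  tp <- cumsum(pos_sorted)
  fp <- cumsum(!pos_sorted)
  keep <- c(sc[-length(sc)] != sc[-1], TRUE)  # threshold boundaries
  tpr <- c(0, tp[keep] / np)
  fpr <- c(0, fp[keep] / nn)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve (step summation)
#'
#' Interpolation-free summation: each recall increment contributes the
#' precision at its threshold.
#'
#' @inheritParams roc_auc
#' @return Area in `[0, 1]`.
#' @export
prc_auc <- function(positive, scores) {
  positive <- as.logical(positive)
  np <- sum(positive)
  if (np == 0) return(0)
  ord <- order(scores, decreasing = TRUE)
  pos_sorted <- positive[ord]
  sc <- scores[ord]
  tp <- cumsum(pos_sorted)
  fp <- cumsum(!pos_sorted)
  keep <- c(sc[-length(sc)] != sc[-1], TRUE)
  tp <- tp[keep]
  fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: n = %d\n", x$n))
  cat(sprintf("  accuracy %.2f%%  kappa %.3f  MAE %.3f  RMSE %.3f\n",
              x$accuracy, x$kappa, x$mae, x$rmse))
  cat("  per-class:\n")
  pc <- x$per_class
  pc[-1] <- lapply(pc[-1], function(v) round(v, 3))
  print(pc, row.names = FALSE)
  invisible(x)
}
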