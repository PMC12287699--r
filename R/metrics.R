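# Binary-classifier evaluation: thresholding, confusion counts, ROC and
# precision-recall curves with trapezoidal AUCs. Tied scores collapse to a
# single curve point, which gives them half-concordance in the ROC AUC (the
# Mann-Whitney convention).

#' Threshold scores into binary calls
#'
#' A score greater than or equal to the threshold is called positive
#' selection (the boundary is inclusive).
#'
#' @param scores numeric scores in [0, 1].
#' @param threshold decision threshold in [0, 1], default 0.5.
#' @return integer vector of 0/1 labels, names preserved.
#' @export
#' @examples
#' classify(c(0.2, 0.5, 0.9))
classify <- function(scores, threshold = 0.5) {
  if (length(threshold) != 1 || is.na(threshold) || threshold < 0 ||
      threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  if (any(is.na(scores)) || any(scores < 0 | scores > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
  out <- as.integer(scores >= threshold)
  names(out) <- names(scores)
  out
}

.undefined_metric <- function(msg) {
  warning(warningCondition(msg,
                           class = "selcnn_undefined_metric"))
}

#' ROC curve over all distinct thresholds
#'
#' @param scores numeric scores.
#' @param truth binary 0/1 truth of the same length.
#' @return data frame with `threshold`, `fpr`, `tpr`, including the (0,0)
#'   and (1,1) endpoints; attribute `auc` holds the trapezoidal area.
#' @export
roc_curve <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.integer(truth)
  P <- sum(truth == 1); N <- sum(truth == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tie block
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  df <- data.frame(threshold = c(Inf, s[keep]),
                   fpr = c(0, fp / N),
                   tpr = c(0, tp / P))
  if (df$fpr[nrow(df)] < 1 || df$tpr[nrow(df)] < 1)
    df <- rbind(df, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(df$fpr) * (utils::head(df$tpr, -1) +
                               utils::tail(df$tpr, -1)) / 2)
  attr(df, "auc") <- auc
  df
}

#' Precision-recall curve over all distinct thresholds
#'
#' The endpoint at recall 0 uses the precision of the highest-score point.
#'
#' @inheritParams roc_curve
#' @return data frame with `threshold`, `recall`, `precision`; attribute
#'   `auc` holds the trapezoidal area.
#' @export
pr_curve <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.integer(truth)
  P <- sum(truth == 1)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  keep <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  prec <- tp / (tp + fp)
  rec <- tp / P
  df <- data.frame(threshold = c(Inf, s[keep]),
                   recall = c(0, rec),
                   precision = c(prec[1], prec))
  auc <- sum(diff(df$recall) * (utils::head(df$precision, -1) +
                                  utils::tail(df$precision, -1)) / 2)
  attr(df, "auc") <- auc
  df
}

#' Full binary-classifier report
#'
#' Confusion counts and rates at the given threshold, plus ROC and
#' precision-recall curves over all distinct score thresholds with
#' trapezoidal AUCs. With single-class truth the curve AUCs are undefined:
#' they are reported as `NA` together with a `selcnn_undefined_metric`
#' warning rather than a silent number.
#'
#' @param scores numeric scores in [0, 1].
#' @param truth binary 0/1 truth.
#' @param threshold decision threshold (inclusive), default 0.5.
#' @return an object of class `metrics_report`: threshold, TP/TN/FP/FN,
#'   accuracy, TPR, FPR, precision, recall, `roc_auc`, `pr_auc`, and the
#'   two curves.
#' @export
#' @examples
#' compute_report(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))$roc_auc  # 0.75
compute_report <- function(scores, truth, threshold = 0.5) {
  stopifnot(length(scores) == length(truth))
  truth <- as.integer(truth)
  if (!all(truth %in% c(0L, 1L)))
    stop("truth must be binary 0/1", call. = FALSE)
  calls <- classify(scores, threshold)
  TP <- sum(calls == 1 & truth == 1)
  TN <- sum(calls == 0 & truth == 0)
  FP <- sum(calls == 1 & truth == 0)
  FN <- sum(calls == 0 & truth == 1)
  n <- length(truth)
  single_class <- length(unique(truth)) < 2
  if (single_class) {
    .undefined_metric("ROC/PR AUC undefined for single-class truth")
    roc <- NULL; pr <- NULL
    roc_auc <- NA_real_; pr_auc <- NA_real_
  } else {
    roc <- roc_curve(scores, truth)
    pr <- pr_curve(scores, truth)
    roc_auc <- attr(roc, "auc")
    pr_auc <- attr(pr, "auc")
  }
  structure(list(threshold = threshold, TP = TP, TN = TN, FP = FP, FN = FN,
                 n = n, accuracy = (TP + TN) / n,
                 tpr = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
                 fpr = if (FP + TN > 0) FP / (FP + TN) else NA_real_,
                 precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
                 recall = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
                 roc_auc = roc_auc, pr_auc = pr_auc,
                 roc = roc, pr = pr),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Binary classifier report (threshold %.3g, n = %d)\n",
              x$threshold, x$n))
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d\n", x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("  accuracy %.4f  TPR %.4f  FPR %.4f\n",
              x$accuracy, x$tpr, x$fpr))
  cat(sprintf("  precision %.4f  recall %.4f\n", x$precision, x$recall))
  cat(sprintf("  ROC AUC %.4f  PR AUC %.4f\n", x$roc_auc, x$pr_auc))
  invisible(x)
}

#' Ingest an externally produced CODEML result table
#'
#' Adapter for side-by-side reports against likelihood-ratio tests run
#' outside this package. No likelihood computation happens here: the file
#' must already contain per-gene results, as a TSV with columns `gene_id`
#' and either `pvalue` (smaller means stronger evidence for selection;
#' scores are taken as `1 - pvalue`) or `score`.
#'
#' @param path TSV file.
#' @return data frame with `gene_id` and `score`.
#' @export
read_codeml_results <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!("gene_id" %in% names(tab)))
    stop("CODEML table must have a gene_id column", call. = FALSE)
  if ("score" %in% names(tab)) {
    data.frame(gene_id = tab$gene_id, score = tab$score)
  } else if ("pvalue" %in% names(tab)) {
    data.frame(gene_id = tab$gene_id, score = 1 - tab$pvalue)
  } else {
    stop("CODEML table must have a pvalue or score column", call. = FALSE)
  }
}
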