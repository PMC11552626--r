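# Threshold-free evaluation: ROC/AUC (exact Mann-Whitney, ties = 1/2),
# step-interpolated AUPRC, Monte Carlo CV aggregation, paired comparison.

#' Compute threshold-free classification metrics
#'
#' AUC is the Mann-Whitney concordance probability (tied scores count 1/2),
#' computed from average ranks, and equals the trapezoidal area under the
#' returned ROC points. AUPRC uses step-wise interpolation (precision at
#' each threshold times the recall increment), which avoids the optimism of
#' linear interpolation in precision-recall space.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1), same length.
#' @return A `metric_report`: `auc`, `auprc`, `roc_points` (fpr, tpr),
#'   `pr_points` (recall, precision), `n_pos`, `n_neg`.
#' @export
compute_metrics <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one positive and one negative (got ", n_pos, "/",
         n_neg, ")")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # ROC / PR over unique score thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  last <- !duplicated(s, fromLast = TRUE)   # last index of each tied block
  tp <- tp[last]; fp <- fp[last]
  tpr <- c(0, tp / n_pos, 1)
  fpr <- c(0, fp / n_neg, 1)
  roc <- data.frame(fpr = fpr, tpr = tpr)

  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  auprc <- sum(diff(c(0, recall)) * precision)
  pr <- data.frame(recall = c(0, recall), precision = c(1, precision))

  structure(list(auc = auc, auprc = auprc, roc_points = roc, pr_points = pr,
                 n_pos = n_pos, n_neg = n_neg),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("AUC %.4f  AUPRC %.4f  (%d pos / %d neg)\n",
              x$auc, x$auprc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Aggregate per-fold metrics, optionally with a paired model comparison
#'
#' Reports the fold mean and standard deviation of AUC and AUPRC. When a
#' second list of fold reports is supplied (same folds, same seeds), a
#' two-sided paired test on per-fold AUC gives the p-value for the
#' labeled-versus-unlabeled comparison.
#'
#' @param fold_reports List of `metric_report`, one per fold.
#' @param paired_reports Optional second list (same length, same fold order).
#' @param test `"t"` (paired t-test, default) or `"wilcoxon"`.
#' @return A `cv_summary`: per-fold table, means/sds, and, when paired,
#'   `delta_auc` (mean fold AUC difference, first minus second) and `p_value`.
#' @export
summarize_cv <- function(fold_reports, paired_reports = NULL,
                         test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(fold_reports) < 2L) stop("need at least 2 folds")
  get <- function(reports, f) vapply(reports, `[[`, numeric(1L), f)
  auc <- get(fold_reports, "auc")
  auprc <- get(fold_reports, "auprc")
  out <- list(per_fold = data.frame(fold = seq_along(auc), auc = auc,
                                    auprc = auprc),
              mean_auc = mean(auc), sd_auc = stats::sd(auc),
              mean_auprc = mean(auprc), sd_auprc = stats::sd(auprc),
              delta_auc = NA_real_, p_value = NA_real_, test = test)
  if (!is.null(paired_reports)) {
    if (length(paired_reports) != length(fold_reports)) {
      stop("paired_reports must have the same number of folds (",
           length(fold_reports), " vs ", length(paired_reports), ")")
    }
    auc2 <- get(paired_reports, "auc")
    d <- auc - auc2
    out$delta_auc <- mean(d)
    out$per_fold$auc_paired <- auc2
    if (stats::sd(d) == 0) {
      out$p_value <- if (all(d == 0)) 1 else 0
    } else if (test == "t") {
      out$p_value <- stats::t.test(auc, auc2, paired = TRUE)$p.value
    } else {
      out$p_value <- stats::wilcox.test(auc, auc2, paired = TRUE,
                                        exact = FALSE)$p.value
    }
  }
  structure(out, class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("CV over %d folds: AUC %.4f +/- %.4f, AUPRC %.4f +/- %.4f\n",
              nrow(x$per_fold), x$mean_auc, x$sd_auc, x$mean_auprc,
              x$sd_auprc))
  if (!is.na(x$delta_auc)) {
    cat(sprintf("paired comparison: delta AUC %.4f, %s-test p = %.4g\n",
                x$delta_auc, x$test, x$p_value))
  }
  invisible(x)
}

#' Export a CV summary as CSV (per fold) and JSON (aggregate)
#' @param summary A `cv_summary`.
#' @param csv_path,json_path Output files (either may be `NULL`).
#' @export
export_cv_summary <- function(summary, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(summary$per_fold, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    agg <- summary[c("mean_auc", "sd_auc", "mean_auprc", "sd_auprc",
                     "delta_auc", "p_value", "test")]
    jsonlite::write_json(agg, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(summary)
}
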