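# Discrimination metrics for integer risk scores: rank-statistic AUC,
# percentile-bootstrap CIs, the upper-left-corner optimal threshold, and
# confusion-matrix metrics at a threshold.

#' Area under the ROC curve (rank statistic)
#'
#' The probability that a random outcome-positive case outscores a random
#' negative, counting ties as one half (Mann–Whitney formulation).
#'
#' @param scores Numeric score vector.
#' @param outcome Binary outcome vector (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, outcome) {
  outcome <- as.integer(outcome)
  n1 <- sum(outcome == 1L); n0 <- sum(outcome == 0L)
  if (n1 == 0L || n0 == 0L)
    stop2("metric error: both outcome classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[outcome == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Sensitivity and specificity at every candidate threshold (the sorted
#' unique scores plus a "predict nobody" sentinel), under the convention
#' that `score >= threshold` predicts positive.
#'
#' @inheritParams auc
#' @return Data frame with `threshold`, `sensitivity`, `specificity`.
#' @export
roc_curve <- function(scores, outcome) {
  outcome <- as.integer(outcome)
  th <- c(sort(unique(scores)), Inf)
  sens <- vapply(th, function(t) mean(scores[outcome == 1L] >= t), 0)
  spec <- vapply(th, function(t) mean(scores[outcome == 0L] < t), 0)
  data.frame(threshold = th, sensitivity = sens, specificity = spec)
}

#' Percentile bootstrap CI for the AUC
#'
#' Case-resampling bootstrap; resamples that lose an outcome class are
#' redrawn (up to 10 retries each). Deterministic given the seed.
#'
#' @inheritParams auc
#' @param n_resamples Number of bootstrap resamples (at least 100;
#'   default 1000).
#' @param seed Integer seed.
#' @param level Coverage (default 0.95).
#' @return Named vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(scores, outcome, n_resamples = 1000L, seed = 1L,
                         level = 0.95) {
  if (n_resamples < 100L) stop2("need at least 100 bootstrap resamples")
  n <- length(scores)
  stats <- with_seed(substream_seed(seed, "bootstrap"), {
    vapply(seq_len(n_resamples), function(b) {
      for (try in 1:10) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(outcome[idx])) == 2L)
          return(auc(scores[idx], outcome[idx]))
      }
      stop2("bootstrap error: could not draw a two-class resample in 10 tries")
    }, 0)
  })
  a <- (1 - level) / 2
  setNames(unname(quantile(stats, c(a, 1 - a), type = 7)), c("lower", "upper"))
}

#' Optimal threshold: nearest point to the ROC upper-left corner
#'
#' Minimizes `(1 - sensitivity)^2 + (1 - specificity)^2` over the candidate
#' thresholds; ties resolve to the lower threshold. Classification rule:
#' `score >= threshold` predicts positive.
#'
#' @param roc A data frame from [roc_curve()].
#' @return The optimal threshold.
#' @export
optimal_threshold <- function(roc) {
  d2 <- (1 - roc$sensitivity)^2 + (1 - roc$specificity)^2
  cand <- which(d2 == min(d2))
  min(roc$threshold[cand])
}

#' Confusion-matrix metrics at a threshold
#'
#' Positive class is outcome 1; `score >= threshold` predicts positive;
#' `F1 = 2 * precision * recall / (precision + recall)` (reported as 0 with
#' a warning when there are no predicted positives).
#'
#' @inheritParams auc
#' @param threshold Classification threshold.
#' @return Named vector `c(accuracy, sensitivity, specificity, f1)`.
#' @export
threshold_metrics <- function(scores, outcome, threshold) {
  outcome <- as.integer(outcome)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & outcome == 1L); fp <- sum(pred == 1L & outcome == 0L)
  fn <- sum(pred == 0L & outcome == 1L); tn <- sum(pred == 0L & outcome == 0L)
  acc <- (tp + tn) / length(outcome)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (tp + fp == 0L) {
    warn2("no predicted positives at threshold ", threshold, "; F1 reported as 0")
    0
  } else {
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  c(accuracy = acc, sensitivity = sens, specificity = spec, f1 = f1)
}

#' Full ROC evaluation of a score
#'
#' Bundles the ROC curve, rank-statistic AUC, percentile-bootstrap 95% CI,
#' the upper-left-corner optimal threshold, and the threshold metrics.
#'
#' @inheritParams bootstrap_ci
#' @return An object of class `roc_result`.
#' @export
evaluate_score <- function(scores, outcome, n_resamples = 1000L, seed = 1L) {
  roc <- roc_curve(scores, outcome)
  a <- auc(scores, outcome)
  ci <- bootstrap_ci(scores, outcome, n_resamples = n_resamples, seed = seed)
  th <- optimal_threshold(roc)
  structure(list(roc = roc, auc = a, ci = ci,
                 n_resamples = as.integer(n_resamples), seed = as.integer(seed),
                 threshold = th,
                 metrics = threshold_metrics(scores, outcome, th)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), optimal threshold %s\n",
              x$auc, x$ci["lower"], x$ci["upper"], format(x$threshold)))
  m <- x$metrics
  cat(sprintf("  accuracy %.3f  sensitivity %.3f  specificity %.3f  F1 %.3f\n",
              m["accuracy"], m["sensitivity"], m["specificity"], m["f1"]))
  invisible(x)
}
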