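#' Confusion-matrix metrics
#'
#' Standard binary metrics at a fixed prediction: sensitivity (recall),
#' specificity, precision, F1, G-mean (geometric mean of sensitivity and
#' specificity) and accuracy. Precision and F1 are reported as missing when no
#' positive prediction was made.
#'
#' @param labels 0/1 vector of true labels (both classes present).
#' @param predictions 0/1 vector of predicted labels.
#' @return list with `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `precision`, `f1`, `g_mean`, `accuracy`.
#' @export
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
confusion_metrics <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop_cfg("labels and predictions differ in length (%d vs %d)",
             length(labels), length(predictions))
  }
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  assert_that(all(labels %in% 0:1) && all(predictions %in% 0:1),
              "labels and predictions must be 0/1")
  assert_that(length(unique(labels)) == 2,
              "labels must contain both classes")
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  fn <- sum(labels == 1 & predictions == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens, specificity = spec, precision = prec, f1 = f1,
       g_mean = sqrt(sens * spec),
       accuracy = (tp + tn) / length(labels))
}

#' ROC and precision-recall curves with their areas
#'
#' The ROC curve is traced over the distinct score thresholds (ties grouped)
#' and its area integrated by the trapezoidal rule — equivalent to the
#' probability that a random positive outscores a random negative, with ties
#' counting one half. The precision-recall curve is integrated by step-wise
#' (right-continuous) interpolation, which avoids the optimism of linear
#' interpolation between PR points.
#'
#' @param labels 0/1 vector (both classes present).
#' @param scores real-valued scores, larger meaning more positive.
#' @return list with `auc_roc`, `pr_auc`, `roc` (data.frame fpr/tpr/threshold)
#'   and `pr` (data.frame recall/precision/threshold).
#' @export
roc_pr_curves <- function(labels, scores) {
  labels <- as.integer(labels)
  assert_that(length(labels) == length(scores),
              "labels and scores differ in length")
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop_cfg("both classes required to trace curves")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp_cum <- cumsum(l)
  fp_cum <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)  # last index within each tie group
  tp <- tp_cum[last]; fp <- fp_cum[last]; th <- s[last]
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  auc_roc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  rec <- tp / np
  prec <- tp / (tp + fp)
  # step interpolation: each recall increment is credited the precision at
  # the threshold achieving it
  pr_auc <- sum(diff(c(0, rec)) * prec)
  list(auc_roc = auc_roc, pr_auc = pr_auc,
       roc = data.frame(fpr = fpr, tpr = tpr, threshold = c(Inf, th)),
       pr = data.frame(recall = rec, precision = prec, threshold = th))
}

#' Stratified bootstrap percentile confidence interval for a metric
#'
#' Resamples positives and negatives separately (preserving the class split),
#' recomputes the metric on each resample, and returns the percentile
#' interval.
#'
#' @param metric_fn function of `(labels, scores)` returning a scalar.
#' @param labels 0/1 vector.
#' @param scores scores or predictions passed through to `metric_fn`.
#' @param reps bootstrap replicates (default 2000; at least 100).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return list with `lower`, `upper`, `level`, `reps`.
#' @export
bootstrap_ci <- function(metric_fn, labels, scores, reps = 2000, seed = NULL,
                         level = 0.95) {
  assert_that(reps >= 100, "bootstrap needs at least 100 replicates")
  labels <- as.integer(labels)
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  assert_that(length(pos) > 0 && length(neg) > 0,
              "both classes required for a stratified bootstrap")
  vals <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      metric_fn(labels[idx], scores[idx])
    }, numeric(1))
  })
  q <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                       na.rm = TRUE, names = FALSE)
  list(lower = q[1], upper = q[2], level = level, reps = reps)
}

#' Choose a classification threshold on training scores
#'
#' Policies: `fixed_0.5` always returns 0.5; `youden_max` maximises
#' sensitivity + specificity - 1; `gmean_max` (the default operating point
#' for imbalanced screening) maximises the geometric mean of sensitivity and
#' specificity. Search is over midpoints between consecutive distinct scores;
#' with perfectly separated classes this lands mid-gap.
#'
#' @param labels 0/1 training labels.
#' @param scores training scores.
#' @param policy `"gmean_max"`, `"youden_max"` or `"fixed_0.5"`.
#' @return numeric threshold; scores at or above it predict positive.
#' @export
choose_threshold <- function(labels, scores,
                             policy = c("gmean_max", "youden_max",
                                        "fixed_0.5")) {
  policy <- match.arg(policy)
  if (policy == "fixed_0.5") return(0.5)
  labels <- as.integer(labels)
  s <- sort(unique(scores))
  cand <- if (length(s) > 1) {
    c(s[1] - 1e-9, (utils::head(s, -1) + utils::tail(s, -1)) / 2,
      s[length(s)] + 1e-9)
  } else s
  np <- sum(labels == 1); nn <- sum(labels == 0)
  crit <- vapply(cand, function(th) {
    pred <- as.integer(scores >= th)
    sens <- sum(pred == 1 & labels == 1) / np
    spec <- sum(pred == 0 & labels == 0) / nn
    if (policy == "gmean_max") sqrt(sens * spec) else sens + spec - 1
  }, numeric(1))
  cand[which.max(crit)]
}

#' Evaluate a score vector on held-out labels
#'
#' Applies the threshold, computes the confusion metrics, the ROC and PR
#' areas, and stratified bootstrap confidence intervals for both areas.
#'
#' @param labels 0/1 test labels.
#' @param scores test scores.
#' @param threshold decision threshold (scores >= threshold predict 1).
#' @param boot_reps bootstrap replicates for the CIs (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `eval_report`: list with `threshold`, the
#'   confusion metrics, `auc_roc`, `auc_roc_ci`, `pr_auc`, `pr_auc_ci`,
#'   `boot_reps`.
#' @export
evaluate_scores <- function(labels, scores, threshold, boot_reps = 2000,
                            seed = NULL) {
  cm <- confusion_metrics(labels, as.integer(scores >= threshold))
  curves <- roc_pr_curves(labels, scores)
  auc_ci <- bootstrap_ci(function(l, s) roc_pr_curves(l, s)$auc_roc,
                         labels, scores, reps = boot_reps,
                         seed = child_seed(seed %||% 0, 1))
  pr_ci <- bootstrap_ci(function(l, s) roc_pr_curves(l, s)$pr_auc,
                        labels, scores, reps = boot_reps,
                        seed = child_seed(seed %||% 0, 2))
  structure(c(list(threshold = threshold), cm,
              list(auc_roc = curves$auc_roc,
                   auc_roc_ci = c(auc_ci$lower, auc_ci$upper),
                   pr_auc = curves$pr_auc,
                   pr_auc_ci = c(pr_ci$lower, pr_ci$upper),
                   boot_reps = boot_reps)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    paste0("threshold %.3f | sens %.3f spec %.3f prec %.3f F1 %.3f ",
           "G-mean %.3f acc %.3f\nAUC-ROC %.3f (%.3f-%.3f)  PR-AUC %.3f ",
           "(%.3f-%.3f)\n"),
    x$threshold, x$sensitivity, x$specificity, x$precision, x$f1, x$g_mean,
    x$accuracy, x$auc_roc, x$auc_roc_ci[1], x$auc_roc_ci[2], x$pr_auc,
    x$pr_auc_ci[1], x$pr_auc_ci[2]))
  invisible(x)
}
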