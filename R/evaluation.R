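# Model evaluation: ROC / PR curves, AUCs and stratified k-fold CV.
#
# Ties in scores receive half credit (the Mann-Whitney convention), so the
# trapezoid ROC AUC equals the rank statistic P(score+ > score-) + 0.5 P(tie).

#' @keywords internal
as_positive <- function(labels, positive = "elinc") {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels > 0)
  as.character(labels) == positive
}

#' ROC curve and area under it
#'
#' Sweeps thresholds over the distinct scores (predicting positive at
#' `score >= threshold`); AUC by the trapezoid rule, equal to the
#' Mann-Whitney rank statistic with half credit for ties.
#'
#' @param scores numeric scores, larger = more positive-like.
#' @param labels class labels; `positive` names the positive class, or pass
#'   a logical/+1-1 vector.
#' @param positive positive-class label (default "elinc").
#' @return list(points = data.frame(fpr, tpr), auc).
#' @export
roc_auc <- function(scores, labels, positive = "elinc") {
  pos <- as_positive(labels, positive)
  if (all(pos) || !any(pos)) stopf("both classes must be present")
  np <- sum(pos); nn <- sum(!pos)
  # rank-statistic AUC (midranks give half credit to ties)
  rk <- rank(scores)
  auc <- (sum(rk[pos]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  last <- !duplicated(scores[ord], fromLast = TRUE)  # one point per threshold
  pts <- data.frame(fpr = c(0, fp[last] / nn), tpr = c(0, tp[last] / np))
  list(points = pts, auc = auc)
}

#' Precision-recall curve and area under it
#'
#' Threshold sweep over distinct scores; AUC by step-wise interpolation
#' (the sum of precision times the recall increment at each threshold).
#'
#' @inheritParams roc_auc
#' @return list(points = data.frame(recall, precision), auc).
#' @export
pr_auc <- function(scores, labels, positive = "elinc") {
  pos <- as_positive(labels, positive)
  if (!any(pos)) stopf("at least one positive required")
  np <- sum(pos)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  pred_pos <- seq_along(ord)
  last <- !duplicated(scores[ord], fromLast = TRUE)
  recall <- tp[last] / np
  precision <- tp[last] / pred_pos[last]
  auc <- sum(diff(c(0, recall)) * precision)
  list(points = data.frame(recall = recall, precision = precision),
       auc = auc)
}

#' Classification accuracy and confusion counts under the sign rule
#'
#' @param scores numeric scores; `> 0` predicts positive (scores of exactly
#'   0 count as negative predictions).
#' @inheritParams roc_auc
#' @return list(accuracy, confusion = c(TP, FP, TN, FN)).
#' @export
sign_accuracy <- function(scores, labels, positive = "elinc") {
  pos <- as_positive(labels, positive)
  pred <- scores > 0
  confusion <- c(TP = sum(pred & pos), FP = sum(pred & !pos),
                 TN = sum(!pred & !pos), FN = sum(!pred & pos))
  list(accuracy = unname((confusion["TP"] + confusion["TN"]) / length(pos)),
       confusion = confusion)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Fits the model on each training fold and pools the held-out scores;
#' accuracy (sign rule), ROC and PR metrics are computed on the pooled
#' out-of-fold scores, as well as per fold.
#'
#' @param X feature matrix.
#' @param y labels ("elinc"/"canonical" or +1/-1).
#' @param alpha,lambda model hyperparameters; `lambda = "cv"` re-selects
#'   lambda on each training fold by an inner [lambda_path_cv()].
#' @param k folds (default 10); `k = n` gives leave-one-out.
#' @param seed RNG seed for fold assignment.
#' @param ... passed to [regnet_fit()].
#' @return list with `accuracy`, `confusion`, `auc_roc`, `auc_pr`,
#'   `roc_points`, `pr_points`, pooled out-of-fold `scores`, `fold` ids and
#'   per-fold accuracy `fold_accuracy`.
#' @export
cross_validate <- function(X, y, alpha, lambda, k = 10, seed, ...) {
  X <- as.matrix(X)
  yv <- as_response(y)
  if (nrow(X) < k) stopf("n < k")
  fold <- make_folds(yv, k, seed)
  scores <- numeric(nrow(X))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    lam <- lambda
    if (identical(lambda, "cv")) {
      lam <- lambda_path_cv(X[tr, , drop = FALSE], yv[tr], alpha,
                            k = min(k, sum(tr)), seed = seed)$chosen
    }
    m <- regnet_fit(X[tr, , drop = FALSE], yv[tr], alpha, lam, ...)
    scores[!tr] <- regnet_score(m, X[!tr, , drop = FALSE])
  }
  acc <- sign_accuracy(scores, yv)
  roc <- roc_auc(scores, yv)
  pr <- pr_auc(scores, yv)
  fold_accuracy <- vapply(sort(unique(fold)), function(f)
    sign_accuracy(scores[fold == f], yv[fold == f])$accuracy, numeric(1))
  list(accuracy = acc$accuracy, confusion = acc$confusion,
       auc_roc = roc$auc, auc_pr = pr$auc,
       roc_points = roc$points, pr_points = pr$points,
       scores = scores, fold = fold, fold_accuracy = fold_accuracy)
}

#' Write ROC/PR points and summary metrics
#' @param eval result of [cross_validate()].
#' @param prefix output path prefix; writes `<prefix>_metrics.tsv`,
#'   `<prefix>_roc.csv`, `<prefix>_pr.csv`.
#' @export
write_eval <- function(eval, prefix) {
  metrics <- data.frame(metric = c("accuracy", "auc_roc", "auc_pr",
                                   names(eval$confusion)),
                        value = c(eval$accuracy, eval$auc_roc, eval$auc_pr,
                                  unname(eval$confusion)))
  utils::write.table(metrics, paste0(prefix, "_metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(eval$roc_points, paste0(prefix, "_roc.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(eval$pr_points, paste0(prefix, "_pr.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
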