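# Evaluation: confusion metrics, ROC/AUC, learning-rate sweep, stratified
# k-fold cross-validation. Malignant is the positive class throughout.

#' Confusion counts and derived metrics
#'
#' Tabulates the 2x2 confusion matrix with malignant as the positive class
#' and derives sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)` and
#' accuracy. A metric whose denominator class is absent from the truth is
#' reported as `NA` (undefined), never as 0.
#'
#' @param truth,predicted Equal-length vectors of `"benign"`/`"malignant"`.
#' @return An `eval_report` list with `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stopf("truth and predicted must have equal length")
  if (!all(c(truth, predicted) %in% dot_labels()))
    stopf("labels must be 'benign' or 'malignant'")
  tp <- sum(truth == "malignant" & predicted == "malignant")
  fn <- sum(truth == "malignant" & predicted == "benign")
  tn <- sum(truth == "benign" & predicted == "benign")
  fp <- sum(truth == "benign" & predicted == "malignant")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 accuracy = (tp + tn) / length(truth)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> tp %d fp %d tn %d fn %d | sens %.3f spec %.3f acc %.3f",
              x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity, x$accuracy))
  if (!is.null(x$auc)) cat(sprintf(" auc %.3f", x$auc))
  cat("\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the distinct scores (plus sentinels so
#' the curve runs from (0,0) to (1,1)), accumulating the true- and
#' false-positive rates, and integrates by the trapezoidal rule. Tied scores
#' contribute a single ROC point, so the trapezoid across a tie grants half
#' credit and the AUC equals the Mann-Whitney statistic: the probability
#' that a random malignant case outscores a random benign one, ties counted
#' half.
#'
#' @param scores Numeric malignant-class scores.
#' @param truth Labels; both classes must be present.
#' @return List with `roc_points` (data frame `fpr`, `tpr`, `threshold`,
#'   sorted by increasing FPR) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.character(truth)
  stopifnot(length(scores) == length(truth))
  pos <- truth == "malignant"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stopf("ROC requires both classes in the truth labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # one point per distinct score: cumulative counts at each tie-group end
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(p)[last_of_group] / n_pos, 1)
  fpr <- c(0, cumsum(!p)[last_of_group] / n_neg, 1)
  thr <- c(Inf, s[last_of_group], -Inf)
  keep <- !duplicated(cbind(fpr, tpr))
  roc <- data.frame(fpr = fpr[keep], tpr = tpr[keep], threshold = thr[keep])
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc_points = roc, auc = auc)
}

#' Evaluate a trained network on a labelled dataset
#'
#' Runs inference, tabulates confusion metrics at the 0.5 threshold, and
#' attaches the full ROC curve and AUC.
#'
#' @param params Trained `network_params`.
#' @param dataset A `slice_dataset` containing both classes.
#' @return An `eval_report` with confusion counts, sensitivity, specificity,
#'   accuracy, `roc_points`, and `auc`.
#' @export
evaluate_classifier <- function(params, dataset) {
  pred <- predict_network(params, dataset)
  rep <- confusion_metrics(dataset$meta$label, pred$label)
  roc <- roc_auc(pred$score, dataset$meta$label)
  rep$roc_points <- roc$roc_points
  rep$auc <- roc$auc
  rep
}

#' Train and evaluate across a grid of learning rates
#'
#' Trains one model per learning rate from a common initialization seed and
#' data split, and evaluates each on the monitor set, enabling an ROC
#' comparison across rates. The default grid brackets the published best
#' rate 0.3 by half-decades.
#'
#' @param train_set,monitor_set `slice_dataset`s.
#' @param rates Non-empty numeric vector of learning rates.
#' @param config Base [train_config()]; its learning rate is overridden.
#' @return Named list (one entry per rate, in input order) of `eval_report`s,
#'   each with the rate and training history attached.
#' @export
learning_rate_sweep <- function(train_set, monitor_set,
                                rates = c(0.03, 0.1, 0.3, 1.0, 3.0),
                                config = train_config()) {
  if (length(rates) == 0L) stopf("rates must be non-empty")
  out <- vector("list", length(rates))
  names(out) <- as.character(rates)
  for (i in seq_along(rates)) {
    cfg <- config
    cfg$learning_rate <- rates[i]
    fit <- train_network(init_params(cfg$seed), train_set, monitor_set, cfg)
    rep <- evaluate_classifier(fit$params, monitor_set)
    rep$learning_rate <- rates[i]
    rep$best_epoch <- fit$best_epoch
    out[[i]] <- rep
  }
  out
}

# Class-stratified fold assignment: within each class, shuffled indices are
# dealt round-robin into k folds, so fold sizes differ by at most one per
# class.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Partitions the dataset into `k` class-stratified folds; each round trains
#' on `k-1` folds (the held-out fold doubles as the early-stopping monitor,
#' as in the published protocol) and evaluates on the held-out fold.
#'
#' @param dataset A `slice_dataset`.
#' @param k Number of folds (>= 2, at most the minority-class count).
#' @param config A [train_config()].
#' @param seed Seed for the fold assignment.
#' @return List with `folds` (per-fold `eval_report`s), `accuracy_mean`,
#'   `accuracy_sd`, `auc_mean`, `auc_sd` (across folds).
#' @export
kfold_cv <- function(dataset, k = 10L, config = train_config(), seed = 1L) {
  labels <- as.character(dataset$meta$label)
  n_min <- min(table(factor(labels, levels = dot_labels())))
  if (!(is_count(k) && k >= 2L)) stopf("k must be an integer >= 2")
  if (k > n_min)
    stopf("k = %d exceeds the minority class count (%d)", k, n_min)
  fold <- stratified_folds(labels, k, seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    train_set <- subset_dataset(dataset, which(fold != f))
    test_set <- subset_dataset(dataset, which(fold == f))
    fit <- train_network(init_params(config$seed), train_set, test_set, config)
    reports[[f]] <- evaluate_classifier(fit$params, test_set)
  }
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  auc <- vapply(reports, `[[`, numeric(1), "auc")
  list(folds = reports,
       accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
       auc_mean = mean(auc), auc_sd = stats::sd(auc))
}
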