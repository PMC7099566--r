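test_that("SGD momentum update follows the velocity recurrence", {
  p <- init_params(1)
  zero_g <- dotcad:::map_leaves(function(x) x * 0, zero_velocity(p))
  # zero gradient, zero velocity: fixed point
  upd <- sgd_momentum_step(p, zero_g, zero_velocity(p), 0.3, 0.9)
  expect_identical(upd$params$conv1$W, p$conv1$W)
  expect_identical(upd$params$fc$W, p$fc$W)
  # momentum 0 reduces to plain gradient descent
  g <- dotcad:::map_leaves(function(x) x * 0 + 0.1, zero_velocity(p))
  upd <- sgd_momentum_step(p, g, zero_velocity(p), 0.5, 0)
  expect_equal(upd$params$fc$W, p$fc$W - 0.5 * 0.1, tolerance = 1e-12)
  # two steps with constant gradient: displacement -lr*g*(2+m)
  m <- 0.9; lr <- 0.2
  s1 <- sgd_momentum_step(p, g, zero_velocity(p), lr, m)
  s2 <- sgd_momentum_step(s1$params, g, s1$velocity, lr, m)
  expect_equal(s2$params$fc$W, p$fc$W - lr * 0.1 * (2 + m), tolerance = 1e-12)
})

test_that("training learns a linearly separable toy set and is deterministic", {
  ds <- make_toy_dataset(20, seed = 5)
  cfg <- train_config(learning_rate = 0.3, batch_size = 10, max_epochs = 50,
                      patience = 50, seed = 9)
  fit <- train_network(init_params(9), ds, ds, cfg)
  expect_lte(min(fit$history$train_mcr), 0)   # reaches zero within 50 epochs
  expect_equal(fit$history$monitor_mcr[fit$best_epoch],
               min(fit$history$monitor_mcr))
  # early stopping never returns params worse than any earlier epoch
  rep <- evaluate_classifier(fit$params, ds)
  expect_gte(1 - rep$accuracy - 1e-12, 0 - 1e-12)
  expect_lte(1 - rep$accuracy, min(fit$history$monitor_mcr) + 1e-12)
  fit2 <- train_network(init_params(9), ds, ds, cfg)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$history, fit2$history)
})

test_that("a flat monitored MCR stops training after patience + 1 epochs", {
  # single-class training drives the monitor MCR to 0 in epoch 1; 0 cannot
  # be improved, so training must stop after exactly patience + 1 epochs
  ds <- make_count_dataset(20, 0)
  mon <- make_count_dataset(4, 0)
  cfg <- train_config(learning_rate = 0.3, batch_size = 10, max_epochs = 100,
                      patience = 3, seed = 2)
  fit <- train_network(init_params(2), ds, mon, cfg)
  expect_equal(fit$history$monitor_mcr[1], 0)
  expect_true(fit$stopped_early)
  expect_equal(nrow(fit$history), cfg$patience + 1L)
  expect_equal(fit$best_epoch, 1L)
})

test_that("training without early stopping runs to max_epochs", {
  ds <- make_toy_dataset(4, seed = 3)
  cfg <- train_config(batch_size = 4, max_epochs = 3, patience = 50, seed = 1)
  fit <- train_network(init_params(1), ds, ds, cfg)
  expect_false(fit$stopped_early)
  expect_equal(nrow(fit$history), 3L)
  expect_error(train_network(init_params(1), ds, make_count_dataset(0, 0),
                             cfg), "non-empty")
})

test_that("prediction scores are probabilities with the benign tie-break", {
  p <- init_params(4)
  p$fc$W[] <- 0; p$fc$b[] <- 0   # zero logits: score exactly 0.5
  imgs <- array(runif(32 * 32 * 6), c(32, 32, 6))
  pred <- predict_network(p, imgs)
  expect_equal(pred$score, rep(0.5, 6))
  expect_true(all(pred$label == "benign"))
  p2 <- init_params(4)
  pred2 <- predict_network(p2, imgs)
  expect_true(all(pred2$score >= 0 & pred2$score <= 1))
})

test_that("confusion metrics match direct arithmetic and a tabulation oracle", {
  all_right <- confusion_metrics(rep(c("benign", "malignant"), 5),
                                 rep(c("benign", "malignant"), 5))
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)
  expect_equal(all_right$accuracy, 1)
  # tp=95 fn=5 tn=80 fp=20
  truth <- rep(c("malignant", "benign"), c(100, 100))
  pred <- c(rep("malignant", 95), rep("benign", 5),
            rep("benign", 80), rep("malignant", 20))
  r <- confusion_metrics(truth, pred)
  expect_equal(r$sensitivity, 0.95)
  expect_equal(r$specificity, 0.80)
  expect_equal(r$accuracy, 0.875)
  # randomized cases vs an independent table() oracle
  set.seed(30)
  for (i in 1:20) {
    t_ <- sample(dot_labels(), 50, replace = TRUE)
    p_ <- sample(dot_labels(), 50, replace = TRUE)
    if (length(unique(t_)) < 2) next
    r <- confusion_metrics(t_, p_)
    tab <- table(factor(t_, dot_labels()), factor(p_, dot_labels()))
    expect_identical(c(r$tp, r$fn, r$tn, r$fp),
                     c(tab["malignant", "malignant"], tab["malignant", "benign"],
                       tab["benign", "benign"], tab["benign", "malignant"]))
  }
  # absent class: affected metric undefined, not zero
  onesided <- confusion_metrics(rep("benign", 5), rep("benign", 5))
  expect_true(is.na(onesided$sensitivity))
  expect_equal(onesided$specificity, 1)
  expect_error(confusion_metrics(c("benign"), c("benign", "malignant")),
               "length")
})

test_that("ROC endpoints, monotonicity, and degenerate AUCs are correct", {
  truth <- rep(c("malignant", "benign"), each = 5)
  perfect <- roc_auc(c(rep(0.9, 5), rep(0.1, 5)), truth)
  expect_equal(perfect$auc, 1.0)
  ties <- roc_auc(rep(0.4, 10), truth)
  expect_equal(ties$auc, 0.5)
  reversed <- roc_auc(c(rep(0.1, 5), rep(0.9, 5)), truth)
  expect_equal(reversed$auc, 0.0)
  set.seed(31)
  r <- roc_auc(runif(60), sample(dot_labels(), 60, replace = TRUE,
                                 prob = c(0.6, 0.4)))
  expect_equal(r$roc_points$fpr[1], 0); expect_equal(r$roc_points$tpr[1], 0)
  expect_equal(r$roc_points$fpr[nrow(r$roc_points)], 1)
  expect_equal(r$roc_points$tpr[nrow(r$roc_points)], 1)
  expect_true(all(diff(r$roc_points$fpr) >= 0))
  expect_true(all(diff(r$roc_points$tpr) >= 0))
  expect_error(roc_auc(runif(5), rep("benign", 5)), "both classes")
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney statistic", {
  set.seed(32)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    truth <- sample(dot_labels(), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    expect_lt(abs(roc_auc(scores, truth)$auc - mann_whitney_auc(scores, truth)),
              1e-12)
  }
})

test_that("stratified k-fold cross-validation partitions and aggregates correctly", {
  labels <- rep(c("benign", "malignant"), c(86, 40))
  fold <- dotcad:::stratified_folds(labels, 10, seed = 5)
  expect_true(all(table(fold) %in% c(12, 13)))
  for (f in 1:10) {
    expect_true(sum(fold == f & labels == "benign") %in% c(8, 9))
    expect_equal(sum(fold == f & labels == "malignant"), 4)
  }
  # minimum-size stratification: k=2 on 2+2 gives one of each per fold
  ds4 <- make_toy_dataset(2, seed = 6)
  cv <- kfold_cv(ds4, k = 2, train_config(batch_size = 2, max_epochs = 1,
                                          patience = 1, seed = 1), seed = 3)
  expect_length(cv$folds, 2L)
  # mean equals independent re-summation of the per-fold accuracies
  accs <- vapply(cv$folds, `[[`, numeric(1), "accuracy")
  expect_equal(cv$accuracy_mean, sum(accs) / 2, tolerance = 1e-12)
  expect_equal(cv$auc_sd, stats::sd(vapply(cv$folds, `[[`, numeric(1), "auc")),
               tolerance = 1e-12)
  expect_error(kfold_cv(ds4, k = 5, train_config(), seed = 1), "minority")
})

test_that("learning-rate sweep is ordered, deterministic, and consistent with direct training", {
  ds <- make_toy_dataset(6, seed = 8)
  cfg <- train_config(batch_size = 6, max_epochs = 4, patience = 4, seed = 11)
  sweep1 <- learning_rate_sweep(ds, ds, rates = 0.3, config = cfg)
  expect_length(sweep1, 1L)
  direct <- evaluate_classifier(
    train_network(init_params(11), ds, ds, cfg)$params, ds)
  expect_equal(sweep1[[1]]$auc, direct$auc, tolerance = 1e-12)
  expect_equal(sweep1[[1]]$accuracy, direct$accuracy, tolerance = 1e-12)
  sweep2 <- learning_rate_sweep(ds, ds, rates = c(0.1, 0.3), config = cfg)
  expect_identical(names(sweep2), c("0.1", "0.3"))
  expect_equal(sweep2[["0.3"]]$auc, sweep1[[1]]$auc, tolerance = 1e-12)
  expect_error(learning_rate_sweep(ds, ds, rates = numeric(0)), "non-empty")
})
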