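test_that("trapezoid AUC matches the pairwise-concordance oracle", {
  set.seed(1)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    scores <- round(runif(n), sample(c(1, 2, 6), 1))   # induce ties
    expect_equal(roc_auc(scores, pos), oracle_auc(scores, pos),
                 tolerance = 1e-9)
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  pos <- rep(c(TRUE, FALSE), each = 50)
  scores <- ifelse(pos, rnorm(100, 0.6, 0.2), rnorm(100, 0.4, 0.2))
  ref <- as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, pos), ref, tolerance = 1e-9)
})

test_that("ROC endpoints, null behaviour and degenerate input", {
  set.seed(3)
  pos <- runif(400) < 0.5
  scores <- runif(400)                       # independent of labels
  expect_lt(abs(roc_auc(scores, pos) - 0.5), 0.05)
  rc <- roc_curve(scores, pos)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_error(roc_curve(scores, rep(TRUE, 400)), "single class")
})

test_that("evaluation metrics are consistent with the confusion matrix", {
  dat <- theta_signal_data(n = 300, seed = 11)
  sp <- split_train_test(dat, seed = 11)
  fit <- train_rf(sp$train, ntrees = 200, repeats = 2, seed = 12)
  ev <- evaluate_model(fit, sp$test)
  cm <- ev$confusion
  expect_equal(ev$accuracy, sum(diag(cm)) / sum(cm))
  expect_equal(ev$sensitivity,
               cm["positive", "positive"] / sum(cm[, "positive"]))
  expect_equal(ev$specificity,
               cm["negative", "negative"] / sum(cm[, "negative"]))
  expect_equal(ev$auc, oracle_auc(ev$scores, ev$labels), tolerance = 1e-9)
  expect_gt(ev$auc, 0.75)       # planted signal is learnable
  td <- tidy(ev)
  expect_equal(td$value[td$metric == "auc"], ev$auc)
  pr <- ev$pr
  expect_equal(pr$recall[nrow(pr)], 1)
  expect_true(all(pr$precision >= 0 & pr$precision <= 1))
})

test_that("a perfectly separating score gives AUC and accuracy 1", {
  dat <- theta_signal_data(n = 80, seed = 13)
  dat$label <- rep(c("positive", "negative"), 40)
  # train on a copy whose first feature encodes the label outright
  dat$r_eff <- ifelse(dat$label == "positive", 1, 0)
  fit <- train_rf(dat, ntrees = 50, repeats = 1, seed = 1)
  ev <- evaluate_model(fit, dat)
  expect_equal(ev$auc, 1)
  expect_equal(ev$accuracy, 1)
})

test_that("permutation importance ranks planted theta signal on top", {
  dat <- theta_signal_data(n = 400, seed = 14)
  sp <- split_train_test(dat, seed = 14)
  fit <- train_rf(sp$train, ntrees = 300, repeats = 2, seed = 15)
  imp <- feature_importance(fit, sp$test, k = 10, seed = 16)
  top3 <- imp$feature[1:3]
  expect_true(all(c("theta_eff", "theta_tgt") %in% top3))
  # a signal-free feature cannot matter much
  expect_lt(imp$importance[imp$feature == "DC_eff"], 0.05)
})

test_that("ablation reports one row per nested subset, full model first", {
  dat <- theta_signal_data(n = 240, seed = 17)
  sp <- split_train_test(dat, seed = 17)
  ab1 <- ablation_study(sp$train, sp$test, n_models = 1,
                        ntrees = 100, repeats = 1, seed = 18)
  expect_equal(nrow(ab1), 1)
  expect_equal(ab1$n_features, 14)

  ab <- ablation_study(sp$train, sp$test,
                       removal_order = c("theta_eff", "theta_tgt", "r_eff",
                                         "r_tgt", "DC_eff", "DC_tgt",
                                         "BC_eff", "BC_tgt"),
                       n_models = 3, ntrees = 100, repeats = 1, seed = 18)
  expect_equal(ab$n_features, c(14, 12, 10))
  # masking both planted-signal features must hurt the AUC
  expect_gt(ab$auc[1], ab$auc[2])
  # masking pure-noise features barely moves it
  noise <- ablation_study(sp$train, sp$test,
                          removal_order = c("DC_eff", "DC_tgt"),
                          n_models = 2, step = 2,
                          ntrees = 200, repeats = 1, seed = 18)
  expect_lt(abs(noise$auc[1] - noise$auc[2]), 0.05)
})
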