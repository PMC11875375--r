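#' ROC curve by threshold sweep
#'
#' Sweeps every distinct score as a decision threshold (plus the trivial
#' endpoints) and records the false- and true-positive rates, giving the
#' empirical ROC step curve.
#'
#' @param scores Numeric vector of predicted probabilities.
#' @param labels Vector coercible to logical positives (`"positive"` /
#'   `TRUE` marks the PTM class).
#' @return Tibble `threshold`, `fpr`, `tpr`, ordered from the strictest
#'   threshold (0, 0) to the laxest (1, 1).
#' @export
roc_curve <- function(scores, labels) {
  pos <- as_positive(labels)
  if (all(pos) || !any(pos)) {
    stop("ROC is undefined when the data contain a single class", call. = FALSE)
  }
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  P <- sum(pos)
  N <- sum(!pos)
  out <- purrr::map_dfr(th, function(t) {
    pred <- scores >= t
    tibble::tibble(threshold = t,
                   fpr = sum(pred & !pos) / N,
                   tpr = sum(pred & pos) / P)
  })
  dplyr::distinct(out, .data$fpr, .data$tpr, .keep_all = TRUE)
}

#' Area under the ROC curve (trapezoid rule)
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`. For tied scores this equals the Mann-Whitney
#'   concordance probability with ties counted one half.
#' @export
roc_auc <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

#' Precision-recall curve
#'
#' @inheritParams roc_curve
#' @return Tibble `threshold`, `recall`, `precision` (precision at zero
#'   predictions is reported as 1).
#' @export
pr_curve <- function(scores, labels) {
  pos <- as_positive(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  P <- sum(pos)
  purrr::map_dfr(th, function(t) {
    pred <- scores >= t
    tp <- sum(pred & pos)
    tibble::tibble(threshold = t,
                   recall = tp / P,
                   precision = if (sum(pred) == 0) 1 else tp / sum(pred))
  })
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) return(labels == "positive")
  as.logical(labels)
}

#' Evaluate a trained model on a labeled test set
#'
#' Scores the test pairs, forms the confusion matrix at `threshold`
#' (default 0.5) and reports accuracy, sensitivity (`TP/(TP+FN)`, recall of
#' the PTM class), specificity (`TN/(TN+FP)`), the ROC curve with its
#' trapezoid AUC, and the precision-recall curve.
#'
#' @param model A `ptm_rf` model.
#' @param test Labeled feature tibble (disjoint from training).
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class `ptm_eval`: list with `confusion` (2x2
#'   table), `accuracy`, `sensitivity`, `specificity`, `auc`, `roc`, `pr`,
#'   `threshold`, `scores`, `labels`.
#' @export
evaluate_model <- function(model, test, threshold = 0.5) {
  scores <- stats::predict(model, test)
  pos <- as_positive(test$label)
  if (all(pos) || !any(pos)) {
    stop("test set contains a single class; ROC undefined", call. = FALSE)
  }
  pred <- scores >= threshold
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  confusion <- matrix(c(tn, fp, fn, tp), nrow = 2,
                      dimnames = list(predicted = c("negative", "positive"),
                                      actual = c("negative", "positive")))
  structure(list(
    confusion = confusion,
    accuracy = (tp + tn) / length(pos),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    auc = roc_auc(scores, pos),
    roc = roc_curve(scores, pos),
    pr = pr_curve(scores, pos),
    threshold = threshold,
    scores = scores,
    labels = pos
  ), class = "ptm_eval")
}

#' @export
print.ptm_eval <- function(x, ...) {
  cat("PTM-PPI model evaluation (threshold", x$threshold, ")\n")
  cat(sprintf("  accuracy %.3f | sensitivity %.3f | specificity %.3f | AUC %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  cat("  confusion matrix (rows = predicted, cols = actual):\n")
  print(x$confusion)
  invisible(x)
}

#' Tidy the headline metrics of an evaluation
#'
#' @param x A `ptm_eval` object.
#' @param ... Unused.
#' @return Long tibble with columns `metric`, `value`.
#' @export
tidy.ptm_eval <- function(x, ...) {
  tibble::tibble(
    metric = c("accuracy", "sensitivity", "specificity", "auc"),
    value = c(x$accuracy, x$sensitivity, x$specificity, x$auc)
  )
}

#' @rdname tidy.ptm_eval
#' @return `glance()` returns the same metrics as a one-row tibble plus
#'   `n_test` and `threshold`.
#' @export
glance.ptm_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
                 specificity = x$specificity, auc = x$auc,
                 n_test = length(x$labels), threshold = x$threshold)
}

#' Permutation feature importance
#'
#' For each feature, permutes its column `k` times (seeded) in the
#' evaluation data and reports the mean drop in accuracy at the model's
#' 0.5 threshold relative to the unpermuted baseline. Features whose
#' permutation does not hurt accuracy score near (or below) zero.
#'
#' @param model A `ptm_rf` model.
#' @param data Labeled feature tibble to permute (typically the test set).
#' @param k Permutations per feature (default 20).
#' @param seed Integer seed.
#' @return Tibble `feature`, `importance`, sorted decreasing (ties keep
#'   canonical feature order).
#' @export
feature_importance <- function(model, data, k = 20, seed = 1L) {
  pos <- as_positive(data$label)
  base <- mean((stats::predict(model, data) >= 0.5) == pos)
  set.seed(seed)
  drops <- purrr::map_dbl(model$features, function(f) {
    mean(purrr::map_dbl(seq_len(k), function(i) {
      perm <- data
      perm[[f]] <- sample(perm[[f]])
      base - mean((stats::predict(model, perm) >= 0.5) == pos)
    }))
  })
  tibble::tibble(feature = model$features, importance = drops) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Feature-masking ablation study
#'
#' Trains a series of models on nested feature subsets — the full set
#' first, then successively masking features in `removal_order` — each with
#' the full cross-validation protocol, and reports the test AUC per subset.
#' The default series of five models removes two features per step
#' (14, 12, 10, 8, 6 features).
#'
#' @param train,test Labeled feature tibbles ([split_train_test()] output).
#' @param removal_order Features to mask, most expendable last; defaults to
#'   descending permutation importance computed on the full model.
#' @param n_models Models in the series (default 5).
#' @param step Features removed between consecutive models (default 2).
#' @param ... Passed to [train_rf()] (`ntrees`, `folds`, `repeats`, ...).
#' @param seed Integer seed.
#' @return Tibble `n_features`, `removed` (comma-joined masked features),
#'   `cv_accuracy`, `auc`.
#' @export
ablation_study <- function(train, test, removal_order = NULL, n_models = 5,
                           step = 2, ..., seed = 1L) {
  all_feats <- ptm_feature_names()
  if (is.null(removal_order)) {
    full <- train_rf(train, features = all_feats, seed = seed, ...)
    removal_order <- feature_importance(full, test, seed = seed)$feature
  }
  stopifnot(all(removal_order %in% all_feats))
  out <- list()
  for (i in seq_len(n_models)) {
    n_drop <- (i - 1) * step
    if (n_drop >= length(all_feats)) {
      warning("feature set exhausted after ", i - 1, " models", call. = FALSE)
      break
    }
    dropped <- utils::head(removal_order, n_drop)
    feats <- setdiff(all_feats, dropped)
    fit <- train_rf(train, features = feats,
                    mtry = min(14, length(feats)), seed = seed, ...)
    ev <- evaluate_model(fit, test)
    out[[i]] <- tibble::tibble(
      n_features = length(feats),
      removed = paste(dropped, collapse = ","),
      cv_accuracy = fit$cv_accuracy,
      auc = ev$auc
    )
  }
  dplyr::bind_rows(out)
}
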