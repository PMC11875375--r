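#' Stratified train / test split of labeled directed pairs
#'
#' Splits a labeled feature table into disjoint training (default 70%) and
#' test (30%) partitions, stratified by `label` so both classes keep their
#' proportions; reproducible under `seed`.
#'
#' @param data Data frame with a `label` column (`"positive"` /
#'   `"negative"`).
#' @param train_fraction Fraction routed to the training partition
#'   (default 0.7).
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(data, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            "label" %in% names(data))
  counts <- table(factor(data$label, levels = c("negative", "positive")))
  if (any(counts < 2)) {
    stop("every class needs at least 2 members to split", call. = FALSE)
  }
  set.seed(seed)
  idx <- unlist(lapply(split(seq_len(nrow(data)), data$label), function(i) {
    sample(i, round(train_fraction * length(i)))
  }), use.names = FALSE)
  list(train = tibble::as_tibble(data[sort(idx), ]),
       test = tibble::as_tibble(data[-sort(idx), ]))
}

undersample_idx <- function(labels) {
  by_class <- split(seq_along(labels), labels)
  n_min <- min(lengths(by_class))
  sort(unlist(lapply(by_class, function(i) {
    if (length(i) > n_min) sample(i, n_min) else i
  }), use.names = FALSE))
}

#' Train the directed PTM-PPI random forest
#'
#' Trains a random forest on the 14 features with the full evaluation
#' protocol: k-fold cross-validation repeated `repeats` times inside the
#' training partition, with the majority class randomly under-sampled to
#' the minority size within each fold's training portion; the final model
#' is refit on the (under-sampled) full training partition. Defaults follow
#' the published configuration: 500 trees and `mtry = 14`, i.e. every
#' feature is tried at each split — which disables the forest's feature
#' subsampling and makes it an ensemble of bootstrapped trees (honoured as
#' published; see the vignette).
#'
#' @param train Feature tibble with `label` and the 14 feature columns.
#' @param ntrees Trees in the forest (default 500).
#' @param mtry Features tried per split (default 14, at most 14).
#' @param folds Cross-validation folds (default 5).
#' @param repeats Cross-validation repeats (default 10).
#' @param undersample Balance classes inside each fold (default `TRUE`).
#' @param features Feature columns to use (default all 14); the ablation
#'   study passes subsets.
#' @param seed Integer seed controlling folds, under-sampling and tree
#'   growth.
#' @return An object of class `ptm_rf`: list with the fitted
#'   `randomForest`, `cv` (tibble of per-fold held-out accuracies),
#'   `cv_accuracy` (their mean), `features`, hyperparameters, and the
#'   under-sampling record.
#' @export
train_rf <- function(train, ntrees = 500, mtry = 14, folds = 5, repeats = 10,
                     undersample = TRUE, features = ptm_feature_names(),
                     seed = 1L) {
  stopifnot("label" %in% names(train))
  if (mtry > length(features)) {
    stop("mtry (", mtry, ") exceeds the number of features (",
         length(features), ")", call. = FALSE)
  }
  missing <- setdiff(features, names(train))
  if (length(missing) > 0) {
    stop("training data lacks feature column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  y <- factor(train$label, levels = c("negative", "positive"))
  if (nlevels(droplevels(y)) < 2) {
    stop("both classes must be present to train", call. = FALSE)
  }
  x <- as.data.frame(train[, features])
  set.seed(seed)

  cv_rows <- list()
  balance_log <- list()
  for (rep_i in seq_len(repeats)) {
    fold_of <- integer(length(y))
    for (cls in levels(y)) {
      i <- which(y == cls)
      fold_of[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
    for (f in seq_len(folds)) {
      tr <- which(fold_of != f)
      ho <- which(fold_of == f)
      if (undersample) {
        tr <- tr[undersample_idx(as.character(y[tr]))]
      }
      balance_log[[length(balance_log) + 1L]] <- tibble::tibble(
        repeat_ = rep_i, fold = f,
        n_negative = sum(y[tr] == "negative"),
        n_positive = sum(y[tr] == "positive")
      )
      fit <- randomForest::randomForest(x = x[tr, , drop = FALSE], y = y[tr],
                                        ntree = ntrees, mtry = mtry)
      prob <- stats::predict(fit, x[ho, , drop = FALSE], type = "prob")[, "positive"]
      acc <- mean((prob >= 0.5) == (y[ho] == "positive"))
      cv_rows[[length(cv_rows) + 1L]] <- tibble::tibble(
        repeat_ = rep_i, fold = f, accuracy = acc, n_heldout = length(ho)
      )
    }
  }
  cv <- dplyr::bind_rows(cv_rows)

  final_idx <- if (undersample) undersample_idx(as.character(y)) else seq_along(y)
  final <- randomForest::randomForest(x = x[final_idx, , drop = FALSE],
                                      y = y[final_idx],
                                      ntree = ntrees, mtry = mtry,
                                      importance = TRUE)
  structure(list(
    forest = final,
    cv = cv,
    cv_accuracy = mean(cv$accuracy),
    features = features,
    ntrees = ntrees, mtry = mtry, folds = folds, repeats = repeats,
    undersample = undersample,
    balance = dplyr::bind_rows(balance_log),
    seed = seed
  ), class = "ptm_rf")
}

#' @export
print.ptm_rf <- function(x, ...) {
  cat("Directed PTM-PPI random forest\n")
  cat("  features:", length(x$features), " trees:", x$ntrees,
      " mtry:", x$mtry, "\n")
  cat(sprintf("  cross-validated accuracy: %.3f (%d-fold x %d repeats%s)\n",
              x$cv_accuracy, x$folds, x$repeats,
              if (x$undersample) ", under-sampled" else ""))
  invisible(x)
}

#' Predict PTM-PPI probabilities for directed pairs
#'
#' The score of a pair is the fraction of trees voting for the positive
#' (PTM) class.
#'
#' @param object A `ptm_rf` model.
#' @param newdata Feature tibble containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.ptm_rf <- function(object, newdata, ...) {
  x <- as.data.frame(newdata[, object$features])
  as.numeric(stats::predict(object$forest, x, type = "prob")[, "positive"])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-fold cross-validation results of a PTM-PPI forest
#'
#' @param x A `ptm_rf` model.
#' @param ... Unused.
#' @return Tibble with one row per fold x repeat: `repeat_`, `fold`,
#'   `accuracy`, `n_heldout`.
#' @export
tidy.ptm_rf <- function(x, ...) {
  x$cv
}

#' One-row summary of a PTM-PPI forest
#'
#' @param x A `ptm_rf` model.
#' @param ... Unused.
#' @return One-row tibble: `cv_accuracy`, `n_features`, `ntrees`, `mtry`,
#'   `folds`, `repeats`, `undersample`.
#' @export
glance.ptm_rf <- function(x, ...) {
  tibble::tibble(cv_accuracy = x$cv_accuracy,
                 n_features = length(x$features),
                 ntrees = x$ntrees, mtry = x$mtry,
                 folds = x$folds, repeats = x$repeats,
                 undersample = x$undersample)
}
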