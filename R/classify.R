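# SVM classification of control (label 0) vs stressed (label 1) cells on the
# eleven predictors: ot_max, S, V, S_over_V, sphericity, mean, variance,
# entropy, kurtosis, skewness, energy. Predictors are z-scored with training
# statistics only; the decision score is oriented so positive means class 1;
# ROC is traced by sweeping all distinct scores and AUC integrated by the
# trapezoidal rule (equal to the normalized Mann-Whitney U statistic).

#' The eleven predictor column names
#' @export
feature_columns <- function() {
  c("ot_max", "S", "V", "S_over_V", "sphericity",
    "mean", "variance", "entropy", "kurtosis", "skewness", "energy")
}

check_feature_table <- function(table) {
  need <- c(feature_columns(), "label")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stopf("feature table is missing columns: %s", paste(missing, collapse = ", "))
  }
  if (!all(table$label %in% c(0, 1))) stopf("labels must be 0 (control) or 1 (stressed)")
  if (anyNA(table[feature_columns()])) stopf("missing predictor values in feature table")
  invisible(table)
}

#' Stratified train/test split
#'
#' Random stratified split: each class contributes `round(fraction * n_class)`
#' rows to the training set; partitions are disjoint and exhaustive and
#' deterministic given the seed.
#'
#' @param table Feature table (tibble/data.frame) with a `label` column.
#' @param train_fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_dataset <- function(table, train_fraction = 0.6, seed = 1L) {
  if (!all(c(0, 1) %in% table$label)) stopf("both classes must be present")
  cls_n <- table(table$label)
  if (any(cls_n < 2)) stopf("need at least 2 rows per class")
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  idx_train <- integer(0)
  for (lb in c(0, 1)) {
    rows <- which(table$label == lb)
    k <- round(train_fraction * length(rows))
    if (k >= length(rows) || k < 1) {
      stopf("train fraction %.2f leaves an empty train or test set for class %s",
            train_fraction, lb)
    }
    idx_train <- c(idx_train, sample(rows, k))
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  idx_train <- sort(idx_train)
  list(train = tibble::as_tibble(table[idx_train, , drop = FALSE]),
       test = tibble::as_tibble(table[-idx_train, , drop = FALSE]))
}

#' Train the SVM classifier
#'
#' Z-scores the predictors with training statistics only, then fits an SVM
#' (default linear kernel, cost 1). Zero-variance predictors are dropped with
#' a warning and recorded in the fitted object. The fitted object exposes a
#' continuous decision score (positive = class 1) and 0/1 predictions at
#' score threshold 0.
#'
#' @param train Training feature table (see [feature_columns()]).
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param cost SVM cost parameter C.
#' @return An object of class `sperm_svm`.
#' @export
train_svm <- function(train, kernel = c("linear", "radial"), cost = 1) {
  kernel <- match.arg(kernel)
  check_feature_table(train)
  if (!all(c(0, 1) %in% train$label)) stopf("both classes must be present in training data")
  preds <- feature_columns()
  X <- as.matrix(train[preds])
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  dropped <- preds[sdev == 0 | !is.finite(sdev)]
  if (length(dropped)) {
    rlang::warn(sprintf("dropping zero-variance predictor(s): %s",
                        paste(dropped, collapse = ", ")))
  }
  keep <- setdiff(preds, dropped)
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep], "/")
  y <- factor(train$label, levels = c(0, 1))
  fit <- e1071::svm(Z, y, kernel = kernel, cost = cost, scale = FALSE)
  # orientation of decision values: positive must mean class "1"
  dv <- attr(predict(fit, Z[1:2, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  flip <- if (grepl("^1", colnames(dv)[1])) 1 else -1
  structure(
    list(fit = fit, center = mu[keep], scale = sdev[keep], predictors = keep,
         dropped = dropped, kernel = kernel, cost = cost, flip = flip),
    class = "sperm_svm"
  )
}

#' Decision scores of a fitted classifier
#' @param model A `sperm_svm`.
#' @param table Feature table.
#' @return Numeric decision scores (positive = stressed).
#' @export
decision_scores <- function(model, table) {
  Z <- sweep(sweep(as.matrix(table[model$predictors]), 2, model$center),
             2, model$scale, "/")
  dv <- attr(predict(model$fit, Z, decision.values = TRUE), "decision.values")
  model$flip * as.numeric(dv)
}

#' @export
predict.sperm_svm <- function(object, newdata, ...) {
  as.integer(decision_scores(object, newdata) > 0)
}

# ROC curve by sweeping all distinct scores (plus +/- Inf) as thresholds;
# prediction is score > threshold.
.roc_points <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores > t & labels == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores > t & labels == 0) / n0, numeric(1))
  tibble::tibble(fpr = fpr, tpr = tpr, threshold = thr)
}

#' Classification metrics from decision scores
#'
#' Score-level core of the evaluation: confusion counts at decision
#' threshold 0 (positive score predicts class 1), sensitivity, specificity
#' and accuracy in percent, the ROC curve over all distinct scores, and the
#' trapezoidal AUC. With a single-class label vector the confusion metrics
#' are returned and the AUC is flagged undefined (`NA`).
#'
#' @param scores Numeric decision scores (larger = more stressed-like).
#' @param labels Binary labels (0 control, 1 stressed).
#' @return A `classification_report` (see [evaluate_classifier()]).
#' @export
classification_metrics <- function(scores, labels) {
  if (length(scores) != length(labels) || length(scores) == 0) {
    stopf("scores and labels must be nonempty and of equal length")
  }
  pred <- as.integer(scores > 0)
  TP <- sum(pred == 1 & labels == 1); FN <- sum(pred == 0 & labels == 1)
  TN <- sum(pred == 0 & labels == 0); FP <- sum(pred == 1 & labels == 0)
  sens <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_
  acc <- 100 * (TP + TN) / length(labels)
  both <- all(c(0, 1) %in% labels)
  roc <- NULL; auc <- NA_real_
  if (both) {
    roc <- .roc_points(scores, labels)
    auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  }
  structure(
    list(confusion = c(TP = TP, FP = FP, TN = TN, FN = FN),
         sensitivity = sens, specificity = spec, accuracy = acc,
         roc = roc, auc = auc, auc_defined = both, n_test = length(labels),
         scores = scores, labels = labels, hyperparameters = list()),
    class = "classification_report"
  )
}

#' Evaluate a classifier on a test set
#'
#' Confusion counts at decision threshold 0, sensitivity, specificity,
#' accuracy, the ROC curve over all distinct decision scores, and the
#' trapezoidal AUC. With a single-class test set the confusion metrics are
#' returned and the AUC is flagged undefined (`NA`).
#'
#' @param model A `sperm_svm` from [train_svm()].
#' @param test Test feature table.
#' @return A `classification_report`: list with `confusion` (TP, FP, TN,
#'   FN), `sensitivity`, `specificity`, `accuracy` (percent), `roc`
#'   (tibble), `auc`, `n_test` and the model hyperparameters.
#' @export
evaluate_classifier <- function(model, test) {
  if (nrow(test) == 0) stopf("test set is empty")
  report <- classification_metrics(decision_scores(model, test), test$label)
  report$hyperparameters <- list(kernel = model$kernel, cost = model$cost,
                                 dropped = model$dropped)
  report
}

#' Run the full classification step
#'
#' Orchestrates stratified split, SVM training and evaluation, and
#' optionally writes `report.json` and `roc.csv`.
#'
#' @param features Feature table (tibble) or path to a feature CSV.
#' @param train_fraction Training fraction (default 0.6, i.e. the 60/40
#'   split).
#' @param kernel,cost SVM hyperparameters (see [train_svm()]).
#' @param seed Split seed.
#' @param report_json,roc_csv Optional output paths.
#' @return A `classification_report` (invisibly also written to disk when
#'   paths are given), with `split_seed` and `train_fraction` recorded.
#' @export
run_classification <- function(features, train_fraction = 0.6,
                               kernel = "linear", cost = 1, seed = 1L,
                               report_json = NULL, roc_csv = NULL) {
  if (is.character(features)) features <- readr::read_csv(features, show_col_types = FALSE)
  check_feature_table(features)
  parts <- split_dataset(features, train_fraction, seed)
  model <- train_svm(parts$train, kernel = kernel, cost = cost)
  report <- evaluate_classifier(model, parts$test)
  report$split_seed <- seed
  report$train_fraction <- train_fraction
  report$n_train <- nrow(parts$train)
  if (!is.null(report_json)) {
    out <- report[c("confusion", "sensitivity", "specificity", "accuracy",
                    "auc", "n_test", "n_train", "split_seed",
                    "train_fraction", "hyperparameters")]
    jsonlite::write_json(out, report_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(roc_csv) && !is.null(report$roc)) {
    readr::write_csv(report$roc, roc_csv)
  }
  report
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>\n")
  cat(sprintf("  n = %d test cells; confusion TP=%d FP=%d TN=%d FN=%d\n",
              x$n_test, x$confusion["TP"], x$confusion["FP"],
              x$confusion["TN"], x$confusion["FN"]))
  cat(sprintf("  sensitivity %.2f%%, specificity %.2f%%, accuracy %.2f%%\n",
              x$sensitivity, x$specificity, x$accuracy))
  cat(sprintf("  AUC %s\n", if (x$auc_defined) sprintf("%.4f", x$auc) else "undefined (single-class test set)"))
  invisible(x)
}

#' Tidy a classification report
#'
#' @param x A `classification_report`.
#' @param ... Unused.
#' @return One row per metric: `metric`, `value`.
#' @export
tidy.classification_report <- function(x, ...) {
  tibble::tibble(
    metric = c("TP", "FP", "TN", "FN", "sensitivity", "specificity",
               "accuracy", "auc"),
    value = c(unname(x$confusion[c("TP", "FP", "TN", "FN")]),
              x$sensitivity, x$specificity, x$accuracy, x$auc)
  )
}

#' @rdname tidy.classification_report
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(
    n_test = x$n_test, sensitivity = x$sensitivity,
    specificity = x$specificity, accuracy = x$accuracy, auc = x$auc,
    kernel = x$hyperparameters$kernel, cost = x$hyperparameters$cost
  )
}

#' @rdname autoplot.phase_map
#' @export
autoplot.classification_report <- function(object, ...) {
  if (is.null(object$roc)) stopf("no ROC curve (single-class test set)")
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc))
}
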