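test_that("stratified split is exact, disjoint and reproducible", {
  tb <- toy_features(50)
  sp <- split_dataset(tb, 0.6, seed = 3)
  expect_equal(nrow(sp$train), 60)
  expect_equal(nrow(sp$test), 40)
  expect_equal(as.integer(table(sp$train$label)), c(30L, 30L))
  expect_equal(sort(c(sp$train$cell_id, sp$test$cell_id)), sort(tb$cell_id))

  sp2 <- split_dataset(tb, 0.6, seed = 3)
  expect_identical(sp$train$cell_id, sp2$train$cell_id)

  expect_error(split_dataset(tb, 1.0, seed = 1), "empty")
  expect_error(split_dataset(dplyr::filter(tb, label == 0), 0.6, 1),
               "both classes")
})

test_that("SVM training separates well-separated classes and flags degeneracies", {
  tb <- toy_features(40, delta = 5)
  m <- train_svm(tb)
  expect_equal(mean(predict(m, tb) == tb$label), 1)

  tb0 <- tb
  tb0$energy <- 1  # constant predictor is dropped with a warning
  expect_warning(m0 <- train_svm(tb0), "zero-variance")
  expect_true("energy" %in% m0$dropped)

  expect_error(train_svm(dplyr::filter(tb, label == 1)), "both classes")
})

test_that("standardization makes predictions invariant to predictor rescaling", {
  tb <- toy_features(40, delta = 2, seed = 4)
  sp <- split_dataset(tb, 0.6, seed = 1)
  m1 <- train_svm(sp$train)
  s1 <- decision_scores(m1, sp$test)

  rescale <- function(d) { d$S <- d$S * 1000; d }
  m2 <- train_svm(rescale(sp$train))
  s2 <- decision_scores(m2, rescale(sp$test))
  expect_equal(s1, s2, tolerance = 1e-6)

  # leakage check: the standardizer uses training statistics only
  expect_equal(unname(m1$center),
               unname(colMeans(as.matrix(sp$train[m1$predictors]))))
})

test_that("confusion metrics and ROC follow their definitions", {
  # TP=9, FN=1, TN=8, FP=2 at threshold 0
  scores <- c(rep(1, 9), -1, rep(-1, 8), 1, 1)
  labels <- c(rep(1, 10), rep(0, 10))
  rep_ <- classification_metrics(scores, labels)
  expect_equal(unname(rep_$confusion), c(9L, 2L, 8L, 1L))
  expect_equal(rep_$sensitivity, 90)
  expect_equal(rep_$specificity, 80)
  expect_equal(rep_$accuracy, 85)

  # perfectly ordered scores
  perf <- classification_metrics(c(1:5, 6:10), rep(c(0, 1), each = 5))
  expect_equal(perf$auc, 1)
  expect_equal(min(perf$roc$fpr), 0)
  expect_equal(max(perf$roc$tpr), 1)
  expect_true(all(diff(perf$roc$tpr) >= 0))
  expect_true(all(diff(perf$roc$fpr) >= 0))

  # single-class test: confusion defined, AUC flagged undefined
  one <- classification_metrics(rnorm(10), rep(1, 10))
  expect_false(one$auc_defined)
  expect_true(is.na(one$auc))
})

test_that("AUC equals the Mann-Whitney statistic and is 0.5 under the null", {
  set.seed(42)
  scores <- round(rnorm(400), 1)  # ties on purpose
  labels <- rep(c(0, 1), 200)
  rep_ <- classification_metrics(scores, labels)
  expect_equal(rep_$auc, brute_auc(scores, labels), tolerance = 1e-12)

  big <- classification_metrics(rnorm(4000), rep(c(0, 1), each = 2000))
  expect_equal(big$auc, 0.5, tolerance = 0.02)

  # label permutation collapses a real signal to chance
  tb <- toy_features(200, delta = 2, seed = 6)
  sp <- split_dataset(tb, 0.6, seed = 2)
  m <- train_svm(sp$train)
  s <- decision_scores(m, sp$test)
  set.seed(7)
  perm <- classification_metrics(s, sample(sp$test$label))
  expect_lt(abs(perm$auc - 0.5), 0.1)
})

test_that("ROC cross-checks against an independent implementation", {
  set.seed(9)
  tb <- toy_features(60, delta = 1.5)
  sp <- split_dataset(tb, 0.6, seed = 5)
  m <- train_svm(sp$train)
  rep_ <- evaluate_classifier(m, sp$test)
  ref <- pROC::roc(sp$test$label, decision_scores(m, sp$test),
                   quiet = TRUE, direction = "<")
  expect_equal(rep_$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("run_classification is deterministic and validates its schema", {
  tb <- toy_features(40, delta = 3, seed = 10)
  td <- withr::local_tempdir()
  r1 <- run_classification(tb, seed = 17,
                           report_json = file.path(td, "report.json"),
                           roc_csv = file.path(td, "roc.csv"))
  r2 <- run_classification(tb, seed = 17)
  expect_identical(glance(r1), glance(r2))
  expect_true(file.exists(file.path(td, "report.json")))
  js <- jsonlite::read_json(file.path(td, "report.json"))
  expect_equal(js$n_train, 48)
  expect_equal(js$hyperparameters$kernel, "linear")

  bad <- dplyr::select(tb, -"entropy", -"energy")
  expect_error(run_classification(bad), "entropy, energy")

  tidied <- tidy(r1)
  expect_equal(nrow(tidied), 8)
  expect_s3_class(autoplot(r1), "ggplot")
})
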