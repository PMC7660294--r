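test_that("metrics reproduce the published worked examples from their counts", {
  met <- compute_metrics(as_confusion(TN = 34, FN = 4, FP = 0, TP = 16))
  expect_equal(round(100 * met$sensitivity, 2), 80.00)
  expect_equal(round(100 * met$specificity, 2), 100.00)
  expect_equal(round(100 * met$precision, 2), 100.00)
  expect_equal(round(100 * met$accuracy, 2), 92.59)
  expect_equal(round(100 * met$f_score, 2), 88.89)

  met2 <- compute_metrics(as_confusion(TN = 31, FN = 2, FP = 3, TP = 18))
  expect_equal(round(100 * met2$accuracy, 2), 90.74)
  expect_equal(round(100 * met2$sensitivity, 2), 90.00)
})

test_that("a perfect classifier scores 100% everywhere; F is the harmonic mean", {
  met <- compute_metrics(as_confusion(TN = 10, FN = 0, FP = 0, TP = 5))
  expect_equal(unlist(met), c(sensitivity = 1, specificity = 1,
                              precision = 1, accuracy = 1, f_score = 1))
  set.seed(8)
  for (i in 1:20) {
    cnt <- as_confusion(TN = sample(0:50, 1), FN = sample(0:20, 1),
                        FP = sample(0:20, 1), TP = sample(1:50, 1))
    m <- compute_metrics(cnt)
    if (!is.na(m$precision) && !is.na(m$sensitivity) &&
        (m$precision + m$sensitivity) > 0) {
      expect_equal(m$f_score,
                   2 * m$precision * m$sensitivity / (m$precision + m$sensitivity),
                   tolerance = 1e-12)
    }
  }
})

test_that("zero denominators yield NA markers, never an error", {
  met <- compute_metrics(as_confusion(TN = 10, FN = 0, FP = 0, TP = 0))
  expect_true(is.na(met$sensitivity))   # no impaired cases present
  expect_true(is.na(met$precision))
  expect_equal(met$accuracy, 1)
})

test_that("misclassification cost is fn_cost*FN + fp_cost*FP", {
  expect_equal(total_misclassification_cost(
    as_confusion(TN = 159, FN = 14, FP = 35, TP = 42)), 455)
  expect_equal(total_misclassification_cost(
    as_confusion(TN = 1, FN = 0, FP = 0, TP = 1)), 0)
  expect_equal(total_misclassification_cost(
    as_confusion(TN = 0, FN = 1, FP = 0, TP = 0)), 30)
  expect_equal(total_misclassification_cost(
    as_confusion(TN = 0, FN = 2, FP = 3, TP = 0), cost_matrix(10, 2)), 26)
})

test_that("pooled CV counts sum to n; folds are deterministic under seed", {
  ms <- small_cohort_matrices(61)
  tr <- impute_missing_durations(ms$train)
  spec <- classifier_spec("decision_tree", "fine")
  c1 <- cross_validate(tr, spec, k = 5, seed = 12)
  expect_equal(c1$TN + c1$FN + c1$FP + c1$TP, nrow(tr))
  c2 <- cross_validate(tr, spec, k = 5, seed = 12)
  expect_identical(unlist(c1), unlist(c2))
  f1 <- iadlscreen:::stratified_folds(tr$group, 5, seed = 33)
  f2 <- iadlscreen:::stratified_folds(tr$group, 5, seed = 33)
  expect_identical(f1, f2)
  few <- rbind(tr[tr$group == "impaired", ][1:3, ],
               tr[tr$group == "healthy", ][1:10, ])
  expect_error(cross_validate(few, spec, k = 5, seed = 1), "fewer than")
})

test_that("k = n cross-validation degenerates to leave-one-out", {
  m <- cloud_matrix(n_min = 6, n_maj = 8, sep = 6, seed = 2)
  cnt <- cross_validate(m, classifier_spec("knn", "fine"), k = nrow(m),
                        seed = 1)
  expect_equal(cnt$TN + cnt$FN + cnt$FP + cnt$TP, nrow(m))
})

test_that("a 1-NN model memorizes: evaluating on training rows is error-free", {
  m <- cloud_matrix(n_min = 10, n_maj = 15, sep = 1, seed = 7)
  cnt <- evaluate_on_test(m, m[4:20, ], classifier_spec("knn", "fine"))
  expect_equal(cnt$FN + cnt$FP, 0)
})

test_that("a single-class test set reports undefined metrics without crashing", {
  m <- cloud_matrix(n_min = 10, n_maj = 15, sep = 6, seed = 5)
  te <- m[m$group == "healthy", ]
  cnt <- evaluate_on_test(m, te, classifier_spec("decision_tree", "coarse"))
  met <- compute_metrics(cnt)
  expect_true(is.na(met$sensitivity))
  expect_false(is.na(met$specificity))
})

test_that("manifest mismatch between train and test is a schema error", {
  m <- cloud_matrix(n_min = 6, n_maj = 8)
  m2 <- cloud_matrix(n_min = 6, n_maj = 8, p = 3)
  expect_error(evaluate_on_test(m, m2, classifier_spec("lda")), "manifest")
})

test_that("every family in the default suite fits and predicts on synthetic data", {
  ms <- small_cohort_matrices(71)
  tr <- impute_missing_durations(ms$train)
  rule <- fit_imputation_rule(ms$train)
  te <- impute_missing_durations(ms$test, rule, use_labels = FALSE)
  suppressWarnings(
    rep <- run_classifier_suite(tr, te, default_classifier_suite(seed = 2),
                                costs = cost_matrix(), cv_k = 5, seed = 3))
  expect_equal(nrow(rep), 18)                       # 9 families x cv/test
  expect_true(all(is.na(rep$error)))
  expect_true(all(rep$TN + rep$FN + rep$FP + rep$TP ==
                    ifelse(rep$split == "cv", nrow(tr), nrow(te))))
  expect_true(all(rep$cost >= 0))
  # xgboost-backed boosted trees also supported beyond the default nine
  cnt <- evaluate_on_test(tr, te, classifier_spec("boosted_trees", seed = 2))
  expect_equal(cnt$TN + cnt$FN + cnt$FP + cnt$TP, nrow(te))
})

test_that("deterministic families give identical reports on rerun", {
  ms <- small_cohort_matrices(81)
  tr <- impute_missing_durations(ms$train)
  rule <- fit_imputation_rule(ms$train)
  te <- impute_missing_durations(ms$test, rule, use_labels = FALSE)
  specs <- list(classifier_spec("decision_tree", "fine", seed = 4),
                classifier_spec("lda", seed = 4),
                classifier_spec("logistic", seed = 4),
                classifier_spec("knn", "cubic", seed = 4))
  suppressWarnings({
    r1 <- run_classifier_suite(tr, te, specs, cv_k = 5, seed = 5)
    r2 <- run_classifier_suite(tr, te, specs, cv_k = 5, seed = 5)
  })
  expect_identical(r1, r2)
})

test_that("unsupported families and variants are rejected up front", {
  expect_error(classifier_spec("quantum_forest"), "unsupported family")
  expect_error(classifier_spec("svm", "septic"), "unsupported variant")
})
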