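test_that("a missing duration becomes twice its group's column maximum", {
  m <- toy_matrix(
    durations = cbind(c(10, 20, 30, 40),
                      c(200, 150, 0, 80)),   # impaired max of col 2 is 200
    group = c("impaired", "impaired", "impaired", "healthy"))
  out <- impute_missing_durations(m)
  expect_equal(out$tDuration_2[3], 400)
  expect_equal(out$tDuration_2[c(1, 2, 4)], c(200, 150, 80))
})

test_that("a matrix without zeros passes through unchanged", {
  m <- toy_matrix(cbind(c(5, 6), c(7, 8)), c("impaired", "healthy"))
  expect_equal(impute_missing_durations(m), m)
})

test_that("TotalTime is recomputed from imputed durations (hand-checked)", {
  m <- toy_matrix(
    durations = cbind(c(100, 0, 50, 60), c(0, 40, 80, 90)),
    group = c("impaired", "impaired", "healthy", "healthy"))
  out <- impute_missing_durations(m)
  # impaired col1 max 100 -> row2 gets 200; impaired col2 max 40 -> row1 gets 80
  expect_equal(out$tDuration_1, c(100, 200, 50, 60))
  expect_equal(out$tDuration_2, c(80, 40, 80, 90))
  # remaining 6 padded duration columns are all 1
  expect_equal(out$TotalTime, c(100 + 80 + 6, 200 + 40 + 6, 50 + 80 + 6,
                                60 + 90 + 6))
  expect_equal(out$TaskScore, m$TaskScore)          # unchanged
})

test_that("after imputation no labelled duration column contains zero and
           replacements exceed every observed value in their group", {
  co <- generate_cohort(cohort_config(25, 25, 0, 0, seed = 21))
  fm <- build_feature_matrix(co$logs, co$labels)
  rule <- fit_imputation_rule(fm)
  out <- impute_missing_durations(fm, rule)
  dc <- sprintf("tDuration_%d", 1:8)
  expect_true(all(as.matrix(out[, dc]) > 0))
  for (cl in dc) {
    for (g in c("impaired", "healthy")) {
      obs <- fm[[cl]][fm$group == g & fm[[cl]] > 0]
      imputed <- out[[cl]][fm$group == g & fm[[cl]] == 0]
      if (length(imputed) && length(obs))
        expect_true(all(imputed > max(obs)))
    }
  }
})

test_that("unlabeled rows fall back to the pooled training maximum", {
  train <- toy_matrix(cbind(c(10, 300), c(20, 30)),
                      group = c("impaired", "healthy"))
  test <- toy_matrix(cbind(0, 50), group = "impaired")
  rule <- fit_imputation_rule(train)
  out <- impute_missing_durations(test, rule, use_labels = FALSE)
  expect_equal(out$tDuration_1[1], 600)   # 2 x pooled max, not 2 x group max
})

test_that("imputation with no observed nonzero value in scope errors", {
  m <- toy_matrix(cbind(c(0, 0), c(5, 6)), c("impaired", "impaired"))
  m$group <- c("impaired", "impaired")
  expect_error(impute_missing_durations(m), "no observed nonzero")
})

test_that("standardization matches the n-1 sample formula and inverts", {
  m <- toy_matrix(cbind(c(1, 2, 3), c(4, 4, 4)),
                  group = c("impaired", "healthy", "healthy"))
  expect_warning(sm <- standardize_features(m), "zero-variance")
  expect_equal(sm$tDuration_1, c(-1, 0, 1))   # mean 2, sd 1 with n-1
  expect_equal(sm$tDuration_2, c(0, 0, 0))
  # standardized columns have mean 0 and sample sd 1
  expect_equal(mean(sm$tDuration_1), 0, tolerance = 1e-9)
  expect_equal(sd(sm$tDuration_1), 1, tolerance = 1e-9)
  back <- unstandardize_features(sm)
  expect_equal(back$tDuration_1, m$tDuration_1, tolerance = 1e-9)
  expect_equal(back$TotalTime, m$TotalTime, tolerance = 1e-9)
})

test_that("fitted standardization params transfer to a second matrix", {
  tr <- toy_matrix(cbind(c(0, 10), c(1, 3)), c("impaired", "healthy"))
  te <- toy_matrix(cbind(5, 2), "healthy")
  suppressWarnings({   # padded toy columns are constant
    str <- standardize_features(tr)
    ste <- standardize_features(te, attr(str, "standardization"))
  })
  expect_equal(ste$tDuration_1[1], (5 - 5) / sd(c(0, 10)))
  expect_equal(ste$tDuration_2[1], (2 - 2) / sd(c(1, 3)))
})

test_that("the stratified split hits the study's per-class counts exactly", {
  co <- generate_cohort(cohort_config(76, 228, 0, 0, seed = 6))
  fm <- build_feature_matrix(co$logs, co$labels)
  sp <- split_train_test(fm, 56, 194, 20, 34, seed = 10)
  expect_equal(sum(sp$train$group == "impaired"), 56)
  expect_equal(sum(sp$train$group == "healthy"), 194)
  expect_equal(nrow(sp$train), 250)
  expect_equal(sum(sp$test$group == "impaired"), 20)
  expect_equal(sum(sp$test$group == "healthy"), 34)
  expect_equal(nrow(sp$test), 54)
  # disjoint and exhaustive over the input
  expect_length(intersect(sp$train$participant_id, sp$test$participant_id), 0)
  expect_setequal(c(sp$train$participant_id, sp$test$participant_id),
                  fm$participant_id)
  # deterministic under seed
  sp2 <- split_train_test(fm, 56, 194, 20, 34, seed = 10)
  expect_identical(sp$train$participant_id, sp2$train$participant_id)
})

test_that("split errors on short classes and on unknown-group rows", {
  m <- toy_matrix(cbind(c(1, 2, 3)), c("impaired", "healthy", "healthy"))
  expect_error(split_train_test(m, 2, 1, 1, 1, seed = 1), "insufficient")
  m$group[2] <- "unknown"
  expect_error(split_train_test(m, 1, 1, 0, 0, seed = 1), "unknown")
})
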