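test_that("task duration is the END-BEGIN difference; absent tasks score zero", {
  log <- parse_event_log(c("09:01:40.0 TASK_3 BEGIN",
                           "09:02:00.0 M001 ON",
                           "09:02:40.0 TASK_3 END"))
  fv <- extract_features(log)
  expect_equal(unname(fv["tDuration_3"]), 60)
  expect_equal(unname(fv["TaskScore"]), 1)          # other 7 tasks not done
  expect_equal(unname(fv[sprintf("tDuration_%d", c(1:2, 4:8))]), rep(0, 7))
  expect_equal(unname(fv["TotalTime"]), 60)
})

test_that("sensor features tally ON transitions of retained sensors only", {
  fv <- extract_features(toy_log())
  expect_equal(unname(fv["sM005"]), 3)    # hand tally: 2 in task 1, 1 in task 3
  expect_equal(unname(fv["sM002"]), 1)
  expect_equal(unname(fv["Total_sEvents"]), 4)      # M030 is not retained
  expect_equal(unname(fv["tDuration_1"]), 60)
  expect_equal(unname(fv["tDuration_3"]), 100)
  expect_equal(unname(fv["TaskScore"]), 2)
  expect_equal(unname(fv["TotalTime"]), 160)
})

test_that("events outside the first-BEGIN..last-END span are trimmed", {
  log <- parse_event_log(c("09:00:00.0 M001 ON",    # before any task
                           "09:00:30.0 TASK_1 BEGIN",
                           "09:00:40.0 M001 ON",
                           "09:01:00.0 TASK_1 END",
                           "09:05:00.0 M001 ON"))   # after the last task
  fv <- extract_features(log)
  expect_equal(unname(fv["sM001"]), 1)
})

test_that("an END before its BEGIN is a data error naming the task", {
  expect_no_error(extract_features(participant_log("x")))  # no markers is fine
  # the constructor rejects the inverted pair
  expect_error(participant_log("x", markers = data.frame(
    task = c(2L, 2L), boundary = c("BEGIN", "END"), time = c(50, 10))),
    "task 2")
})

test_that("the default manifest has exactly 38 predictors (39 with age)", {
  expect_length(feature_manifest(), 38)
  expect_length(feature_manifest(include_age = TRUE), 39)
  expect_length(default_retained_sensors(), 27)
  expect_false(any(sprintf("M%03d", 27:50) %in% default_retained_sensors()))
})

test_that("feature matrix has one row per log and consistent derived columns", {
  co <- generate_cohort(cohort_config(4, 6, 0, 0, seed = 12))
  fm <- build_feature_matrix(co$logs, co$labels)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(nrow(fm), 10)
  expect_length(predictors(fm), 38)
  sensor_cols <- grep("^sM", predictors(fm), value = TRUE)
  expect_length(sensor_cols, 27)
  expect_equal(fm$Total_sEvents, rowSums(fm[, sensor_cols]))
  expect_equal(fm$TotalTime, rowSums(fm[, sprintf("tDuration_%d", 1:8)]))
  expect_equal(fm$TaskScore,
               rowSums(fm[, sprintf("tDuration_%d", 1:8)] > 0))
  expect_true(all(as.matrix(fm[, predictors(fm)]) >= 0))
})

test_that("zero logs give an empty matrix that still carries the manifest", {
  fm <- build_feature_matrix(list())
  expect_equal(nrow(fm), 0)
  expect_length(predictors(fm), 38)
  expect_true(all(predictors(fm) %in% names(fm)))
})

test_that("duplicate participant ids are rejected", {
  log <- toy_log()
  expect_error(build_feature_matrix(list(log, log)), "duplicate")
})

test_that("shrinking the retained sensor set never increases Total_sEvents", {
  log <- generate_participant_log(healthy_behaviour_params(), seed = 4)
  full <- extract_features(log)
  for (drop_n in c(1, 5, 20)) {
    kept <- default_retained_sensors()[-(seq_len(drop_n))]
    sub <- extract_features(log, retained_sensors = kept)
    expect_lte(unname(sub["Total_sEvents"]), unname(full["Total_sEvents"]))
  }
})

test_that("extraction is invariant to the order of same-time events", {
  lines <- c("09:00:00.0 TASK_1 BEGIN",
             "09:00:05.0 M001 ON",
             "09:00:05.0 M002 ON",
             "09:00:10.0 TASK_1 END")
  f1 <- extract_features(parse_event_log(lines))
  f2 <- extract_features(parse_event_log(lines[c(1, 3, 2, 4)]))
  expect_identical(f1, f2)
})

test_that("feature matrices round trip through CSV with their sidecar", {
  co <- generate_cohort(cohort_config(2, 3, 0, 0, seed = 8))
  fm <- build_feature_matrix(co$logs, co$labels)
  path <- file.path(tempdir(), "fm.csv")
  write_feature_matrix(fm, path)
  fm2 <- read_feature_matrix(path)
  expect_equal(predictors(fm2), predictors(fm))
  expect_equal(as.matrix(fm2[, predictors(fm2)]),
               as.matrix(fm[, predictors(fm)]), tolerance = 1e-9)
})
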