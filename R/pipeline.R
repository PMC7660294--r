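#' Pipeline configuration
#'
#' Bundles every stage's settings.  With \code{simulate = TRUE} the
#' synthetic cohort generator supplies the logs; otherwise \code{logs_dir}
#' and \code{labels_path} must point at CASAS-dialect log files (one per
#' participant, named \code{<participant_id>.txt}) plus a label CSV.
#' Stage seeds are derived deterministically from the master seed by a
#' fixed scheme (stage index keyed), so adding a stage never shifts the
#' random stream of an earlier one.
#'
#' @param out_dir Output directory for artifacts.
#' @param simulate Generate the cohort instead of reading logs.
#' @param cohort A \code{\link{cohort_config}} (when simulating).
#' @param logs_dir,labels_path Input paths (when ingesting).
#' @param dialect A \code{\link{log_dialect}}.
#' @param retained_sensors Sensor ids counted as features.
#' @param include_age Add the Age predictor.
#' @param imputation_mode "class_conditional" or "pooled".
#' @param bins Equal-frequency bins for MRMR.
#' @param balance_method "none", "duplicate" or "smote".
#' @param target_minority Minority target for balancing (default: match
#'   the majority for duplication; 197 in the emulation profile for SMOTE).
#' @param smote_k SMOTE neighbour count.
#' @param specs Classifier spec list.
#' @param costs Optional \code{\link{cost_matrix}}.
#' @param cv_k Cross-validation folds.
#' @param split_sizes Per-class train/test counts used when the input data
#'   carries no split assignment (named list: train_impaired, train_healthy,
#'   test_impaired, test_healthy); defaults emulate the study split.
#' @param seed Master seed.
#' @return Object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir = tempfile("iadlscreen_run_"),
                            simulate = TRUE,
                            cohort = cohort_config(seed = seed),
                            logs_dir = NULL, labels_path = NULL,
                            dialect = log_dialect(),
                            retained_sensors = default_retained_sensors(),
                            include_age = FALSE,
                            imputation_mode = "class_conditional",
                            bins = 10L,
                            balance_method = c("none", "duplicate", "smote"),
                            target_minority = NULL, smote_k = 5L,
                            specs = default_classifier_suite(seed = seed),
                            costs = NULL, cv_k = 5L,
                            split_sizes = list(train_impaired = 56,
                                               train_healthy = 194,
                                               test_impaired = 20,
                                               test_healthy = 34),
                            seed = 1L) {
  balance_method <- match.arg(balance_method)
  structure(list(out_dir = out_dir, simulate = simulate, cohort = cohort,
                 logs_dir = logs_dir, labels_path = labels_path,
                 dialect = dialect, retained_sensors = retained_sensors,
                 include_age = include_age, imputation_mode = imputation_mode,
                 bins = bins, balance_method = balance_method,
                 target_minority = target_minority, smote_k = smote_k,
                 specs = specs, costs = costs, cv_k = cv_k,
                 split_sizes = split_sizes, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(config, stage_index) derive_seed(config$seed, stage_index)

write_sidecar <- function(path, stage, seed, extra = list()) {
  jsonlite::write_json(
    c(list(stage = stage, seed = seed,
           written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra),
    paste0(path, ".meta.json"), auto_unbox = TRUE, pretty = TRUE)
}

pipeline_log <- function(verbose, stage, msg) {
  if (verbose) message(sprintf("[%s] %s", stage, msg))
}

#' Run the full screening pipeline
#'
#' simulate-or-ingest, feature extraction, train/test split, imputation
#' (rule fitted on train, pooled fallback on test), MRMR ranking, optional
#' balancing, classifier suite, report.  Every tabular artifact is written
#' as CSV with a JSON provenance sidecar recording stage and seed.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param verbose Log row counts per stage.
#' @return List with the feature matrix, split, ranking, balanced training
#'   matrix, report table, and the output directory.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- stage 1: simulate or ingest ----------------------------------------
  if (config$simulate) {
    cohort <- generate_cohort(config$cohort)
    logs <- cohort$logs
    labels <- cohort$labels
    pipeline_log(verbose, "simulate", sprintf("%d logs generated", length(logs)))
  } else {
    if (is.null(config$logs_dir) || !dir.exists(config$logs_dir))
      stop("logs directory not found: ", config$logs_dir %||% "<missing>")
    labels <- read_label_table(config$labels_path)
    files <- list.files(config$logs_dir, pattern = "\\.txt$", full.names = TRUE)
    logs <- lapply(files, function(f) {
      pid <- sub("\\.txt$", "", basename(f))
      j <- match(pid, labels$participant_id)
      parse_event_log(f, config$dialect, participant_id = pid,
                      category_code = if (is.na(j)) NA_integer_
                      else labels$category_code[j])
    })
    pipeline_log(verbose, "ingest", sprintf("%d log files read", length(logs)))
  }

  # -- stage 2: extract ----------------------------------------------------
  fm <- build_feature_matrix(logs, labels, config$retained_sensors,
                             config$include_age)
  known <- fm[fm$group %in% c("impaired", "healthy"), , drop = FALSE]
  pipeline_log(verbose, "extract",
               sprintf("%d rows, %d predictors (%d unknown-group rows dropped)",
                       nrow(known), length(predictors(fm)),
                       nrow(fm) - nrow(known)))
  fm_path <- file.path(config$out_dir, "features.csv")
  write_feature_matrix(fm, fm_path, extra = list(stage = "extract"))

  # -- stage 3: split ------------------------------------------------------
  if (config$simulate && "split" %in% names(labels)) {
    # the generator already assigned splits; honour them
    train <- known[labels$split[match(known$participant_id,
                                      labels$participant_id)] == "train", ,
                   drop = FALSE]
    test <- known[labels$split[match(known$participant_id,
                                     labels$participant_id)] == "test", ,
                  drop = FALSE]
  } else {
    sz <- config$split_sizes
    sp <- split_train_test(known, sz$train_impaired, sz$train_healthy,
                           sz$test_impaired, sz$test_healthy,
                           seed = stage_seed(config, 3L))
    train <- sp$train; test <- sp$test
  }
  pipeline_log(verbose, "split", sprintf("train %d / test %d rows",
                                         nrow(train), nrow(test)))
  utils::write.csv(data.frame(participant_id = c(train$participant_id,
                                                 test$participant_id),
                              split = rep(c("train", "test"),
                                          c(nrow(train), nrow(test)))),
                   file.path(config$out_dir, "split.csv"), row.names = FALSE)

  # -- stage 4: impute -----------------------------------------------------
  rule <- fit_imputation_rule(train, config$imputation_mode)
  train <- impute_missing_durations(train, rule, use_labels = TRUE)
  test <- impute_missing_durations(test, rule, use_labels = FALSE)
  write_imputation_rule(rule, file.path(config$out_dir, "imputation_rule.json"))
  pipeline_log(verbose, "impute", "durations imputed (train labelled, test pooled)")

  # -- stage 5: rank -------------------------------------------------------
  ranking <- rank_features_mrmr(train, bins = config$bins)
  write_ranking(ranking, file.path(config$out_dir, "ranking.json"))
  utils::write.csv(ranking, file.path(config$out_dir, "ranking.csv"),
                   row.names = FALSE)
  pipeline_log(verbose, "rank", sprintf("top feature: %s", ranking$feature[1]))

  # -- stage 6: balance ----------------------------------------------------
  train_bal <- train
  if (config$balance_method != "none") {
    mm <- minority_majority(train)
    target <- config$target_minority %||%
      (nrow(train) - mm$n_minority)            # parity with the majority
    train_bal <- if (config$balance_method == "duplicate")
      duplicate_oversample(train, target, seed = stage_seed(config, 6L))
    else
      smote_oversample(train, target, k = config$smote_k,
                       seed = stage_seed(config, 6L))
    pipeline_log(verbose, "balance",
                 sprintf("%s: %d -> %d rows", config$balance_method,
                         nrow(train), nrow(train_bal)))
  }
  bal_path <- file.path(config$out_dir, "train_balanced.csv")
  write_feature_matrix(train_bal, bal_path,
                       extra = list(stage = "balance",
                                    method = config$balance_method,
                                    seed = stage_seed(config, 6L)))

  # -- stage 7: evaluate ---------------------------------------------------
  report <- run_classifier_suite(train_bal, test, config$specs, config$costs,
                                 config$cv_k, seed = stage_seed(config, 7L))
  rep_path <- file.path(config$out_dir, "report.csv")
  utils::write.csv(report, rep_path, row.names = FALSE)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  write_sidecar(rep_path, "evaluate", stage_seed(config, 7L),
                list(cv_k = config$cv_k,
                     cost_fn = if (is.null(config$costs)) NA
                     else config$costs$fn_cost))
  pipeline_log(verbose, "evaluate", sprintf("%d report rows", nrow(report)))

  list(features = fm, train = train, test = test, train_balanced = train_bal,
       ranking = ranking, report = report, out_dir = config$out_dir)
}
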