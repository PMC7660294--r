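#' Fit the class-conditional missing-duration imputation rule
#'
#' A zero task duration means the task was not done; leaving it at 0 s
#' would read as "done very quickly".  The rule replaces each zero with
#' twice the maximum observed nonzero duration of that task within the
#' row's cognitive group.  The rule is fitted on labelled training data
#' only; rows whose label is unavailable at prediction time fall back to
#' twice the maximum over all training groups, so no test label ever
#' enters the fit.
#'
#' @param train A labelled feature matrix (training split).
#' @param mode \code{"class_conditional"} (per-group maxima, the formal
#'   algorithm) or \code{"pooled"} (single per-column maxima).
#' @return Object of class \code{"imputation_rule"}: per group and duration
#'   column the maximum nonzero value (NA when a group/column has none).
#' @export
fit_imputation_rule <- function(train, mode = c("class_conditional", "pooled")) {
  mode <- match.arg(mode)
  cols <- duration_cols()
  stopifnot(all(cols %in% names(train)))
  groups <- c("impaired", "healthy")
  max_nz <- function(v) if (any(v > 0)) max(v[v > 0]) else NA_real_
  per_group <- sapply(cols, function(cl) {
    vapply(groups, function(g) max_nz(train[[cl]][train$group == g]), numeric(1))
  })                                   # 2 x 8 matrix, rows = groups
  pooled <- vapply(cols, function(cl) max_nz(train[[cl]]), numeric(1))
  structure(list(mode = mode, groups = groups, columns = cols,
                 per_group = per_group, pooled = pooled),
            class = "imputation_rule")
}

#' Replace missing (zero) task durations
#'
#' Applies an \code{\link{imputation_rule}}: every zero in a duration
#' column becomes twice the relevant maximum, and TotalTime is recomputed
#' as the new row sum of the eight durations.  TaskScore is left unchanged
#' (it still counts genuinely completed tasks).
#'
#' @param m Feature matrix.
#' @param rule A fitted rule; when NULL the rule is fitted on \code{m}
#'   itself (training use).
#' @param use_labels Use each row's group for the class-conditional lookup;
#'   set FALSE for unlabelled/test data to use the pooled fallback.
#' @return The imputed feature matrix.
#' @export
impute_missing_durations <- function(m, rule = NULL, use_labels = TRUE) {
  if (is.null(rule)) rule <- fit_imputation_rule(m)
  cols <- rule$columns
  for (cl in cols) {
    z <- which(m[[cl]] == 0)
    for (i in z) {
      mx <- if (rule$mode == "pooled" || !use_labels ||
                !(m$group[i] %in% rule$groups)) {
        rule$pooled[[cl]]
      } else {
        rule$per_group[m$group[i], cl]
      }
      if (is.na(mx))
        stop("no observed nonzero ", cl,
             " to impute from (group ", m$group[i], ")")
      m[[cl]][i] <- 2 * mx
    }
  }
  m$TotalTime <- rowSums(m[, cols, drop = FALSE])
  m
}

#' Serialize an imputation rule to JSON for audit
#' @param rule An \code{imputation_rule}.
#' @param path Output path.
#' @export
write_imputation_rule <- function(rule, path) {
  jsonlite::write_json(
    list(mode = rule$mode,
         per_group = as.data.frame(rule$per_group),
         pooled = as.list(rule$pooled)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Standardize predictor columns
#'
#' Centers each predictor by its sample mean and scales by its sample
#' standard deviation (n - 1 denominator).  A zero-variance column maps to
#' all zeros with a warning.  Used for the parallel-coordinates style
#' exports; classifiers train on raw features.
#'
#' @param m Feature matrix.
#' @param params Optional previously fitted parameters (fit on train,
#'   apply to test); when NULL they are fitted on \code{m}.
#' @return Standardized matrix with the fitted parameters in
#'   \code{attr(, "standardization")}.
#' @export
standardize_features <- function(m, params = NULL) {
  cols <- predictors(m)
  if (is.null(params)) {
    center <- vapply(cols, function(cl) mean(m[[cl]]), numeric(1))
    scale <- vapply(cols, function(cl) stats::sd(m[[cl]]), numeric(1))
    params <- list(columns = cols, center = center, scale = scale)
  }
  for (cl in params$columns) {
    s <- params$scale[[cl]]
    if (is.na(s) || s == 0) {
      warning("zero-variance column ", cl, " standardized to 0")
      m[[cl]] <- rep(0, nrow(m))
    } else {
      m[[cl]] <- (m[[cl]] - params$center[[cl]]) / s
    }
  }
  attr(m, "standardization") <- params
  m
}

#' @rdname standardize_features
#' @param sm A standardized matrix (or any matrix plus explicit params).
#' @export
unstandardize_features <- function(sm, params = attr(sm, "standardization")) {
  stopifnot(!is.null(params))
  for (cl in params$columns) {
    s <- params$scale[[cl]]
    if (is.na(s) || s == 0) s_use <- 0 else s_use <- s
    sm[[cl]] <- sm[[cl]] * s_use + params$center[[cl]]
  }
  attr(sm, "standardization") <- NULL
  sm
}

#' Stratified train/test split with exact per-class counts
#'
#' Rows with an unknown cognitive group must be removed beforehand (they
#' are discarded from modelling).  Selection is a seeded random sample
#' without replacement; train and test are disjoint and their union covers
#' exactly the selected rows.
#'
#' @param m Feature matrix with a \code{group} column of "impaired"/"healthy".
#' @param n_train_impaired,n_train_healthy,n_test_impaired,n_test_healthy
#'   Exact per-class counts; defaults emulate the study split
#'   (56/194 train, 20/34 test).
#' @param seed Integer seed.
#' @return List with \code{train} and \code{test} feature matrices.
#' @export
split_train_test <- function(m, n_train_impaired = 56, n_train_healthy = 194,
                             n_test_impaired = 20, n_test_healthy = 34,
                             seed = 1L) {
  if (any(!(m$group %in% c("impaired", "healthy"))))
    stop("remove rows with unknown group before splitting")
  take <- function(pool, n_train, n_test, what) {
    if (length(pool) < n_train + n_test)
      stop("insufficient ", what, " rows: need ", n_train + n_test,
           ", have ", length(pool))
    sel <- sample(pool, n_train + n_test)
    list(train = sel[seq_len(n_train)],
         test = sel[n_train + seq_len(n_test)])
  }
  res <- with_seed(seed, {
    imp <- take(which(m$group == "impaired"), n_train_impaired,
                n_test_impaired, "impaired")
    hea <- take(which(m$group == "healthy"), n_train_healthy,
                n_test_healthy, "healthy")
    list(imp = imp, hea = hea)
  })
  train <- m[sort(c(res$imp$train, res$hea$train)), , drop = FALSE]
  test <- m[sort(c(res$imp$test, res$hea$test)), , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test)
}
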