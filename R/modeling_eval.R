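CLASS_LEVELS <- c("healthy", "impaired")  # impaired = positive class

#' Confusion counts with the impaired class positive
#'
#' @param truth,pred Vectors of "healthy"/"impaired".
#' @return Object of class \code{"confusion_counts"} with integer fields
#'   TN, FN, FP, TP.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- factor(as.character(truth), levels = CLASS_LEVELS)
  pred <- factor(as.character(pred), levels = CLASS_LEVELS)
  stopifnot(!anyNA(truth), !anyNA(pred), length(truth) == length(pred))
  as_confusion(TN = sum(truth == "healthy" & pred == "healthy"),
               FN = sum(truth == "impaired" & pred == "healthy"),
               FP = sum(truth == "healthy" & pred == "impaired"),
               TP = sum(truth == "impaired" & pred == "impaired"))
}

#' @rdname confusion_counts
#' @param TN,FN,FP,TP Non-negative integer counts.
#' @export
as_confusion <- function(TN, FN, FP, TP) {
  counts <- c(TN = as.integer(TN), FN = as.integer(FN),
              FP = as.integer(FP), TP = as.integer(TP))
  stopifnot(all(counts >= 0))
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TN=%d FN=%d FP=%d TP=%d\n",
              x$TN, x$FN, x$FP, x$TP))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Confusion-matrix metrics for the impaired (positive) class
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP),
#' accuracy (TP+TN)/total, and the F-score 2TP/(2TP+FP+FN) — the harmonic
#' mean of precision and sensitivity.  A zero denominator yields NA rather
#' than an error.  Values are proportions in [0, 1].
#'
#' @param counts A \code{\link{confusion_counts}}.
#' @return Object of class \code{"metric_set"}.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TN + counts$FN + counts$FP + counts$TP
  stopifnot(total > 0)
  structure(list(
    sensitivity = safe_ratio(counts$TP, counts$TP + counts$FN),
    specificity = safe_ratio(counts$TN, counts$TN + counts$FP),
    precision = safe_ratio(counts$TP, counts$TP + counts$FP),
    accuracy = (counts$TP + counts$TN) / total,
    f_score = safe_ratio(2 * counts$TP, 2 * counts$TP + counts$FP + counts$FN)),
    class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "  --  " else sprintf("%6.2f%%", 100 * v)
  cat(sprintf("sensitivity %s  specificity %s  precision %s  accuracy %s  F %s\n",
              pct(x$sensitivity), pct(x$specificity), pct(x$precision),
              pct(x$accuracy), pct(x$f_score)))
  invisible(x)
}

#' Misclassification cost matrix
#'
#' The screening goal penalises a missed impaired participant far more
#' than a false alarm: the default raises the false-negative cost to 30
#' against a false-positive cost of 1; correct classifications cost 0.
#'
#' @param fn_cost,fp_cost Non-negative costs.
#' @return Object of class \code{"cost_matrix"}.
#' @export
cost_matrix <- function(fn_cost = 30, fp_cost = 1) {
  stopifnot(fn_cost >= 0, fp_cost >= 0)
  structure(list(fn_cost = fn_cost, fp_cost = fp_cost), class = "cost_matrix")
}

#' Total misclassification cost fn_cost * FN + fp_cost * FP
#' @param counts A \code{\link{confusion_counts}}.
#' @param costs A \code{\link{cost_matrix}}.
#' @export
total_misclassification_cost <- function(counts, costs = cost_matrix()) {
  costs$fn_cost * counts$FN + costs$fp_cost * counts$FP
}

SUPPORTED_VARIANTS <- list(
  decision_tree = c("fine", "medium", "coarse"),
  lda = "default",
  logistic = "default",
  kernel_naive_bayes = "default",
  svm = c("quadratic", "cubic", "gaussian", "fine_gaussian"),
  knn = c("fine", "medium", "cubic"),
  bagged_trees = "default",
  boosted_trees = "default",
  rusboosted_trees = "default",
  ffnn = "default")

#' Specify a classifier family and preset variant
#'
#' Families mirror the comparison suite: decision trees (fine/medium/
#' coarse = decreasing maximum depth), linear discriminant, logistic
#' regression, kernel (KDE) naive Bayes, SVM (quadratic/cubic polynomial
#' or Gaussian kernels), KNN (fine k=1; medium k=10; cubic k=10 with
#' Minkowski p=3 distance), bagged trees, gradient-boosted trees,
#' RUSBoosted trees, and a single-hidden-layer feed-forward network.
#'
#' @param family One of the supported family names.
#' @param variant Preset within the family (see Details); defaults to the
#'   family's first preset.
#' @param seed Integer seed used by stochastic learners.
#' @param ... Overrides passed to the underlying learner (e.g.
#'   \code{hidden = 10} for the FFNN, \code{nrounds} for boosting).
#' @return Object of class \code{"classifier_spec"}.
#' @export
classifier_spec <- function(family, variant = NULL, seed = 1L, ...) {
  if (!family %in% names(SUPPORTED_VARIANTS))
    stop("unsupported family: ", family)
  if (is.null(variant)) variant <- SUPPORTED_VARIANTS[[family]][1]
  if (!variant %in% SUPPORTED_VARIANTS[[family]])
    stop("unsupported variant '", variant, "' for family ", family)
  structure(list(family = family, variant = variant, seed = as.integer(seed),
                 opts = list(...)),
            class = "classifier_spec")
}

cost_weight <- function(costs) {
  if (is.null(costs)) 1 else costs$fn_cost / max(costs$fp_cost, .Machine$double.eps)
}

# ---- kernel (KDE) naive Bayes -------------------------------------------

kde_nb_fit <- function(X, y, prior) {
  models <- lapply(CLASS_LEVELS, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    lapply(seq_len(ncol(X)), function(j) {
      v <- Xc[, j]
      bw <- tryCatch(stats::bw.nrd0(v), error = function(e) NA_real_)
      if (!is.finite(bw) || bw <= 0) bw <- max(stats::sd(v), 1e-3)
      list(obs = v, bw = bw)
    })
  })
  names(models) <- CLASS_LEVELS
  list(models = models, prior = prior)
}

kde_density <- function(mod, x) {
  # Gaussian-kernel density at x, floored to avoid log(0)
  d <- mean(stats::dnorm((x - mod$obs) / mod$bw)) / mod$bw
  max(d, 1e-12)
}

kde_nb_predict <- function(fit, X) {
  scores <- sapply(CLASS_LEVELS, function(cl) {
    mods <- fit$models[[cl]]
    lp <- log(fit$prior[[cl]])
    for (j in seq_len(ncol(X)))
      lp <- lp + log(vapply(X[, j], function(x) kde_density(mods[[j]], x),
                            numeric(1)))
    lp
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  CLASS_LEVELS[max.col(scores, ties.method = "first")]
}

# ---- Minkowski KNN -------------------------------------------------------

knn_predict <- function(Xtr, ytr, Xte, k, p = 2, w_pos = 1) {
  apply(Xte, 1, function(row) {
    d <- (rowSums(abs(sweep(Xtr, 2, row))^p))^(1 / p)
    nn <- order(d)[seq_len(min(k, nrow(Xtr)))]
    votes <- ifelse(ytr[nn] == "impaired", w_pos, 1)
    pos <- sum(votes[ytr[nn] == "impaired"])
    neg <- sum(votes[ytr[nn] == "healthy"])
    if (pos >= neg && pos > 0) "impaired" else "healthy"
  })
}

# ---- RUSBoost ------------------------------------------------------------

# AdaBoost with random undersampling of the majority class at each round;
# weak learners are shallow rpart trees.
rusboost_fit <- function(X, y, nrounds = 50, maxdepth = 3, seed = 1L,
                         w_pos = 1) {
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = CLASS_LEVELS)
  n <- nrow(df)
  w <- ifelse(y == "impaired", w_pos, 1)
  w <- w / sum(w)
  mm <- table(y)
  minority <- names(mm)[which.min(mm)]
  majority <- setdiff(CLASS_LEVELS, minority)
  n_min <- min(mm)
  learners <- list(); alphas <- numeric(0)
  with_seed(seed, {
    for (r in seq_len(nrounds)) {
      maj_idx <- which(y == majority)
      keep <- sample(maj_idx, min(n_min, length(maj_idx)),
                     prob = w[maj_idx] / sum(w[maj_idx]))
      idx <- c(which(y == minority), keep)
      fit <- rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE],
                          weights = w[idx] / sum(w[idx]) * length(idx),
                          method = "class",
                          control = rpart::rpart.control(
                            maxdepth = maxdepth, cp = 0, minsplit = 5,
                            xval = 0))
      pred <- predict(fit, df, type = "class")
      miss <- pred != df$.y
      err <- sum(w[miss])
      if (err >= 0.5) next
      alpha <- if (err <= 1e-10) 10 else 0.5 * log((1 - err) / err)
      learners[[length(learners) + 1L]] <- fit
      alphas <- c(alphas, alpha)
      w <- w * exp(alpha * ifelse(miss, 1, -1))
      w <- w / sum(w)
      if (err <= 1e-10) break
    }
  })
  if (!length(learners))
    stop("RUSBoost found no weak learner better than chance")
  list(learners = learners, alphas = alphas)
}

rusboost_predict <- function(fit, X) {
  df <- as.data.frame(X)
  score <- rep(0, nrow(df))
  for (i in seq_along(fit$learners)) {
    pr <- predict(fit$learners[[i]], df, type = "class")
    score <- score + fit$alphas[i] * ifelse(pr == "impaired", 1, -1)
  }
  ifelse(score > 0, "impaired", "healthy")
}

# ---- unified fit/predict -------------------------------------------------

tree_control <- function(variant) {
  switch(variant,
         fine = rpart::rpart.control(maxdepth = 30, cp = 1e-4, minsplit = 5,
                                     xval = 0),
         medium = rpart::rpart.control(maxdepth = 5, cp = 0.005, minsplit = 10,
                                       xval = 0),
         coarse = rpart::rpart.control(maxdepth = 2, cp = 0.01, minsplit = 10,
                                       xval = 0))
}

#' Fit a classifier from a spec
#'
#' Cost sensitivity: trees use a native rpart loss matrix; other families
#' receive the cost ratio fn_cost/fp_cost as a positive-class weight
#' (case weights, class priors, class.weights or vote weights as the
#' learner supports).
#'
#' @param spec A \code{\link{classifier_spec}}.
#' @param train Labelled feature matrix.
#' @param costs Optional \code{\link{cost_matrix}}.
#' @return Object of class \code{"fitted_classifier"}.
#' @export
fit_classifier <- function(spec, train, costs = NULL) {
  cols <- predictors(train)
  X <- as.matrix(train[, cols, drop = FALSE])
  y <- factor(train$group, levels = CLASS_LEVELS)
  stopifnot(!anyNA(y))
  w_pos <- cost_weight(costs)
  case_w <- ifelse(y == "impaired", w_pos, 1)
  df <- as.data.frame(X); df$.y <- y
  opts <- spec$opts

  model <- with_seed(spec$seed, switch(
    spec$family,
    decision_tree = {
      # loss matrix rows = true class (healthy, impaired)
      loss <- matrix(c(0, if (is.null(costs)) 1 else costs$fn_cost,
                       if (is.null(costs)) 1 else costs$fp_cost, 0), 2, 2)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(loss = loss), control = tree_control(spec$variant))
    },
    lda = {
      freq <- prop.table(table(y))
      prior <- freq * c(healthy = 1, impaired = w_pos)
      MASS::lda(X, grouping = y, prior = as.numeric(prior / sum(prior)))
    },
    logistic = {
      stats::glm(.y ~ ., data = df, family = stats::binomial(),
                 weights = case_w)
    },
    kernel_naive_bayes = {
      freq <- prop.table(table(y))
      prior <- freq * c(healthy = 1, impaired = w_pos)
      kde_nb_fit(X, as.character(y), as.list(prior / sum(prior)))
    },
    svm = {
      kern <- switch(spec$variant,
                     quadratic = list(kernel = "polynomial", degree = 2),
                     cubic = list(kernel = "polynomial", degree = 3),
                     gaussian = list(kernel = "radial"),
                     fine_gaussian = list(kernel = "radial",
                                          gamma = 16 / ncol(X)))
      args <- c(list(x = X, y = y, scale = apply(X, 2, stats::sd) > 0,
                     coef0 = if (grepl("polynomial", kern$kernel %||% "")) 1 else 0,
                     class.weights = c(healthy = 1, impaired = w_pos)),
                kern)
      do.call(e1071::svm, args)
    },
    knn = {
      preset <- switch(spec$variant,
                       fine = list(k = 1, p = 2),
                       medium = list(k = 10, p = 2),
                       cubic = list(k = 10, p = 3))
      list(X = X, y = as.character(y), k = preset$k, p = preset$p,
           w_pos = w_pos)
    },
    bagged_trees = {
      randomForest::randomForest(
        X, y, ntree = opts$ntree %||% 200, mtry = ncol(X),
        cutoff = c(healthy = w_pos, impaired = 1) / (w_pos + 1))
    },
    boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y == "impaired"))
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.3, scale_pos_weight = w_pos,
                      nthread = 1, seed = spec$seed),
        data = dtrain, nrounds = opts$nrounds %||% 100, verbose = 0)
    },
    rusboosted_trees = {
      rusboost_fit(X, as.character(y), nrounds = opts$nrounds %||% 50,
                   maxdepth = opts$maxdepth %||% 3, seed = spec$seed,
                   w_pos = w_pos)
    },
    ffnn = {
      ctr <- colMeans(X)
      scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
      Xs <- scale(X, center = ctr, scale = scl)
      net <- nnet::nnet(Xs, class.ind(y), size = opts$hidden %||% 10,
                        decay = opts$decay %||% 0.1,
                        maxit = opts$maxit %||% 300,
                        softmax = TRUE, trace = FALSE,
                        weights = case_w, MaxNWts = 5000)
      list(net = net, center = ctr, scale = scl)
    }))

  structure(list(spec = spec, model = model, columns = cols),
            class = "fitted_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

class.ind <- function(y) {
  m <- matrix(0, length(y), length(CLASS_LEVELS),
              dimnames = list(NULL, CLASS_LEVELS))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

#' Predict cognitive group for new rows
#' @param object A \code{fitted_classifier}.
#' @param newdata Feature matrix with the same predictor manifest.
#' @param ... Unused.
#' @export
predict.fitted_classifier <- function(object, newdata, ...) {
  if (!all(object$columns %in% names(newdata)))
    stop("predictor manifest mismatch")
  X <- as.matrix(newdata[, object$columns, drop = FALSE])
  df <- as.data.frame(X)
  spec <- object$spec
  model <- object$model
  out <- switch(
    spec$family,
    decision_tree = as.character(predict(model, df, type = "class")),
    lda = as.character(predict(model, X)$class),
    logistic = ifelse(stats::predict(model, df, type = "response") > 0.5,
                      "impaired", "healthy"),
    kernel_naive_bayes = kde_nb_predict(model, X),
    svm = as.character(predict(model, X)),
    knn = knn_predict(model$X, model$y, X, model$k, model$p, model$w_pos),
    bagged_trees = as.character(predict(model, X)),
    boosted_trees = ifelse(predict(model, xgboost::xgb.DMatrix(X)) > 0.5,
                           "impaired", "healthy"),
    rusboosted_trees = rusboost_predict(model, X),
    ffnn = {
      Xs <- scale(X, center = model$center, scale = model$scale)
      CLASS_LEVELS[max.col(predict(model$net, Xs), ties.method = "first")]
    })
  factor(unname(out), levels = CLASS_LEVELS)
}

stratified_folds <- function(y, k, seed) {
  if (k == length(y)) return(seq_len(k))   # leave-one-out
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < k)
        stop("class '", cl, "' has fewer than k = ", k, " members")
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Stratified k-fold cross-validation, pooled confusion counts
#'
#' Rows are partitioned into k stratified folds (seeded); each fold is
#' predicted by a model trained on the remaining folds and the confusion
#' counts are pooled so they always sum to the number of rows.
#'
#' @param train Labelled feature matrix.
#' @param spec A \code{\link{classifier_spec}}.
#' @param k Number of folds (default 5).
#' @param costs Optional \code{\link{cost_matrix}}.
#' @param seed Fold-assignment seed.
#' @return A \code{\link{confusion_counts}}.
#' @export
cross_validate <- function(train, spec, k = 5L, costs = NULL, seed = 1L) {
  stopifnot(k >= 2)
  y <- as.character(train$group)
  folds <- stratified_folds(y, k, seed)
  truth <- character(0); pred <- character(0)
  for (f in seq_len(k)) {
    hold <- folds == f
    fit <- fit_classifier(spec, train[!hold, , drop = FALSE], costs)
    pred <- c(pred, as.character(predict(fit, train[hold, , drop = FALSE])))
    truth <- c(truth, y[hold])
  }
  confusion_counts(truth, pred)
}

#' Fit on the full training set and evaluate on a held-out test set
#'
#' @param train,test Feature matrices with identical predictor manifests.
#' @param spec A \code{\link{classifier_spec}}.
#' @param costs Optional \code{\link{cost_matrix}}.
#' @return A \code{\link{confusion_counts}}.
#' @export
evaluate_on_test <- function(train, test, spec, costs = NULL) {
  if (!identical(predictors(train), predictors(test)))
    stop("train and test predictor manifests differ")
  fit <- fit_classifier(spec, train, costs)
  confusion_counts(test$group, predict(fit, test))
}

#' Run a classifier comparison suite
#'
#' One row per spec and split (cv/test) with confusion counts, the metric
#' set, and — when a cost matrix is active — the total misclassification
#' cost.  A single model failure is recorded in its row, not fatal.
#'
#' @param train Labelled training feature matrix.
#' @param test Optional test feature matrix (NULL: test columns NA).
#' @param specs List of \code{\link{classifier_spec}} objects.
#' @param costs Optional \code{\link{cost_matrix}}.
#' @param cv_k Folds for cross-validation.
#' @param seed Fold seed.
#' @return data.frame with columns model, variant, split, TN, FN, FP, TP,
#'   sensitivity, specificity, precision, accuracy, f_score, cost, error.
#' @export
run_classifier_suite <- function(train, test = NULL, specs, costs = NULL,
                                 cv_k = 5L, seed = 1L) {
  stopifnot(length(specs) >= 1)
  row_for <- function(spec, split, counts, err = NA_character_) {
    base <- data.frame(model = spec$family, variant = spec$variant,
                       split = split, TN = NA_integer_, FN = NA_integer_,
                       FP = NA_integer_, TP = NA_integer_,
                       sensitivity = NA_real_, specificity = NA_real_,
                       precision = NA_real_, accuracy = NA_real_,
                       f_score = NA_real_, cost = NA_real_,
                       error = err, stringsAsFactors = FALSE)
    if (!is.null(counts)) {
      met <- compute_metrics(counts)
      base[c("TN", "FN", "FP", "TP")] <- unlist(counts)
      base[c("sensitivity", "specificity", "precision", "accuracy",
             "f_score")] <- unlist(met)
      if (!is.null(costs))
        base$cost <- total_misclassification_cost(counts, costs)
    }
    base
  }
  rows <- list()
  for (spec in specs) {
    cv <- tryCatch(list(counts = cross_validate(train, spec, cv_k, costs, seed)),
                   error = function(e) list(counts = NULL, err = conditionMessage(e)))
    rows[[length(rows) + 1L]] <-
      row_for(spec, "cv", cv$counts, cv$err %||% NA_character_)
    if (!is.null(test) && nrow(test) > 0) {
      te <- tryCatch(list(counts = evaluate_on_test(train, test, spec, costs)),
                     error = function(e) list(counts = NULL, err = conditionMessage(e)))
      rows[[length(rows) + 1L]] <-
        row_for(spec, "test", te$counts, te$err %||% NA_character_)
    } else {
      rows[[length(rows) + 1L]] <- row_for(spec, "test", NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The default nine-model comparison suite
#'
#' Decision tree, linear discriminant, logistic regression, kernel naive
#' Bayes, SVM, KNN, bagged trees, RUSBoosted trees and the feed-forward
#' network, with the presets used throughout the comparison tables.
#'
#' @param tree_variant,svm_variant,knn_variant Preset overrides.
#' @param seed Seed recorded on every spec.
#' @return List of \code{\link{classifier_spec}}.
#' @export
default_classifier_suite <- function(tree_variant = "coarse",
                                     svm_variant = "quadratic",
                                     knn_variant = "cubic", seed = 1L) {
  list(classifier_spec("decision_tree", tree_variant, seed),
       classifier_spec("lda", seed = seed),
       classifier_spec("logistic", seed = seed),
       classifier_spec("kernel_naive_bayes", seed = seed),
       classifier_spec("svm", svm_variant, seed),
       classifier_spec("knn", knn_variant, seed),
       classifier_spec("bagged_trees", seed = seed),
       classifier_spec("rusboosted_trees", seed = seed),
       classifier_spec("ffnn", seed = seed))
}
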