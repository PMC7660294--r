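minority_majority <- function(m) {
  tab <- table(m$group)
  if (length(tab) < 2L) stop("balancing needs both classes present")
  minority <- names(tab)[which.min(tab)]
  list(minority = minority,
       majority = setdiff(names(tab), minority)[1],
       n_minority = as.integer(min(tab)))
}

#' Balance a training matrix by duplicating minority rows
#'
#' Minority rows are resampled with replacement (seeded) until the
#' configured minority count is reached; every added row is an exact copy
#' of an input minority row and the majority class passes through
#' untouched.
#'
#' @param train Labelled feature matrix.
#' @param target_minority_count Desired minority row count (>= current).
#' @param seed Integer seed.
#' @return Balanced feature matrix.
#' @export
duplicate_oversample <- function(train, target_minority_count, seed = 1L) {
  mm <- minority_majority(train)
  if (mm$n_minority == 0) stop("empty minority class")
  if (target_minority_count < mm$n_minority)
    stop("target_minority_count below current minority count")
  n_new <- target_minority_count - mm$n_minority
  if (n_new == 0) return(train)
  min_idx <- which(train$group == mm$minority)
  dup <- with_seed(seed, sample(min_idx, n_new, replace = TRUE))
  out <- rbind(train, train[dup, , drop = FALSE])
  rownames(out) <- NULL
  as_feature_matrix(out, predictors(train))
}

# safe level of each point: minority members among its k nearest
# neighbours over the whole training set (any class), self excluded
safe_levels <- function(X, is_minority, k) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  vapply(seq_len(n), function(i) {
    nn <- order(D[i, ])[seq_len(k)]
    sum(is_minority[nn])
  }, numeric(1))
}

#' Safe-level SMOTE oversampling of the minority class
#'
#' Synthetic minority rows are linear interpolations x + u (x_nn - x)
#' between a minority seed row and one of its k nearest minority
#' neighbours (Euclidean distance on the raw predictors, matching the
#' pipeline's order of operations; set \code{standardize_distances} when
#' raw durations should not dominate).  The interpolation weight u follows
#' the safe-level rule: with sl the count of minority points among a
#' point's k nearest neighbours of any class, u ~ U(0,1) when seed and
#' neighbour are equally safe, u ~ U(0, sl_n/sl_s) when the seed is safer,
#' u ~ U(1 - sl_s/sl_n, 1) when the neighbour is safer, and u = 0
#' (duplicate the seed) when the neighbour's safe level is zero.
#'
#' @param train Labelled feature matrix.
#' @param target_minority_count Desired minority count (>= current).
#' @param k Number of nearest neighbours (default 5); must be smaller than
#'   the minority count.
#' @param seed Integer seed.
#' @param standardize_distances Compute neighbourhoods on standardized
#'   predictors (generation still happens in raw space).
#' @return Balanced feature matrix; synthetic rows get participant ids
#'   \code{smote_<i>}.
#' @export
smote_oversample <- function(train, target_minority_count, k = 5L, seed = 1L,
                             standardize_distances = FALSE) {
  mm <- minority_majority(train)
  if (mm$n_minority <= k)
    stop("minority count (", mm$n_minority, ") must exceed k (", k, ")")
  if (target_minority_count < mm$n_minority)
    stop("target_minority_count below current minority count")
  n_new <- target_minority_count - mm$n_minority
  if (n_new == 0) return(train)

  cols <- predictors(train)
  X <- as.matrix(train[, cols, drop = FALSE])
  if (standardize_distances) {
    sds <- apply(X, 2, stats::sd)
    Xd <- scale(X, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  } else Xd <- X
  is_min <- train$group == mm$minority
  min_idx <- which(is_min)

  sl <- safe_levels(Xd, is_min, k)
  # k nearest minority neighbours of each minority point
  Dm <- as.matrix(stats::dist(Xd[min_idx, , drop = FALSE]))
  diag(Dm) <- Inf

  synth <- with_seed(seed, {
    seeds_local <- sample(rep_len(seq_along(min_idx), n_new))
    out <- matrix(NA_real_, n_new, length(cols),
                  dimnames = list(NULL, cols))
    for (j in seq_len(n_new)) {
      si <- seeds_local[j]                       # index within minority
      nn_pool <- order(Dm[si, ])[seq_len(k)]
      ni <- nn_pool[sample.int(k, 1)]
      sl_s <- sl[min_idx[si]]
      sl_n <- sl[min_idx[ni]]
      u <- if (sl_n == 0) {
        0                                        # unsafe neighbour: copy seed
      } else if (sl_s == 0) {
        1                                        # unsafe seed: copy neighbour side
      } else if (sl_s == sl_n) {
        stats::runif(1)
      } else if (sl_s > sl_n) {
        stats::runif(1, 0, sl_n / sl_s)          # stay near the safer seed
      } else {
        stats::runif(1, 1 - sl_s / sl_n, 1)      # shift toward safer neighbour
      }
      out[j, ] <- X[min_idx[si], ] + u * (X[min_idx[ni], ] - X[min_idx[si], ])
    }
    out
  })

  new_rows <- as.data.frame(synth)
  new_rows$participant_id <- sprintf("smote_%d", seq_len(n_new))
  new_rows$group <- mm$minority
  out <- rbind(train, new_rows[, names(train), drop = FALSE])
  rownames(out) <- NULL
  as_feature_matrix(out, cols)
}
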