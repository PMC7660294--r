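#' Equal-frequency discretization of a continuous column
#'
#' Bins values into at most B codes at the empirical quantiles.  Boundary
#' ties are merged, so the number of distinct codes never exceeds the
#' number of distinct values.  Quantile binning is robust to the heavy
#' right tails of task durations.  Non-numeric input is passed through as
#' integer codes of its distinct values.
#'
#' @param values Numeric (or factor/character) vector.
#' @param bins Maximum number of bins, >= 1.
#' @return Integer codes in 1..bins.
#' @export
discretize_column <- function(values, bins = 10L) {
  stopifnot(bins >= 1)
  if (!is.numeric(values)) return(as.integer(factor(values)))
  if (length(values) == 0L) return(integer(0))
  ux <- sort(unique(values))
  if (length(ux) <= bins) return(match(values, ux))  # already discrete enough
  qs <- stats::quantile(values, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7)
  brk <- unique(qs)
  if (length(brk) < 2L) return(rep(1L, length(values)))
  as.integer(cut(values, breaks = brk, include.lowest = TRUE))
}

#' Plug-in mutual information of two discrete variables
#'
#' The empirical-probability double sum over the joint distribution, in
#' nats: terms with zero joint probability contribute zero; the estimate
#' is 0 when the variables are empirically independent and equals the
#' empirical entropy of \code{x} when \code{z = x}.
#'
#' @param x,z Equal-length vectors of discrete codes.
#' @return Object of class \code{"mi_estimate"} with fields \code{value}
#'   (nats), \code{joint}, \code{px}, \code{pz}.
#' @export
estimate_mutual_information <- function(x, z) {
  if (length(x) != length(z))
    stop("length mismatch: ", length(x), " vs ", length(z))
  stopifnot(length(x) >= 1)
  joint <- table(x, z) / length(x)
  px <- rowSums(joint)
  pz <- colSums(joint)
  outer_p <- outer(px, pz)
  nz <- joint > 0
  value <- sum(joint[nz] * log(joint[nz] / outer_p[nz]))
  structure(list(value = max(value, 0), joint = joint, px = px, pz = pz),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat("<mi_estimate> ", format(x$value), " nats\n", sep = "")
  invisible(x)
}

mi_value <- function(x, z) estimate_mutual_information(x, z)$value

#' MRMR feature ranking by the mutual-information quotient
#'
#' Ranks predictors by forward addition: the first selected feature
#' maximises relevance V (mutual information with the class label); each
#' subsequent step selects the candidate maximising the quotient
#' MIQ = V / W, where W is the mean mutual information between the
#' candidate and the already-selected set.  Continuous predictors are
#' discretized by equal-frequency binning first.  Ties are broken by
#' larger V, then lexicographic feature name; a candidate with W = 0 and
#' V > 0 (independent of everything selected) wins its step outright.
#'
#' @param m Feature matrix with a discrete label column.
#' @param label_col Name of the label column (default "group").
#' @param bins Equal-frequency bins for continuous predictors.
#' @param features Predictor names to rank; defaults to the matrix's
#'   manifest.
#' @return data.frame of class \code{"ranked_features"}: rank, feature,
#'   score (V for step 1, MIQ after), relevance, redundancy.
#' @export
rank_features_mrmr <- function(m, label_col = "group", bins = 10L,
                               features = predictors(m)) {
  stopifnot(length(features) >= 1, all(features %in% names(m)))
  y <- m[[label_col]]
  if (length(unique(y)) < 2L)
    stop("label column '", label_col, "' has zero variance")
  disc <- lapply(features, function(f) discretize_column(m[[f]], bins))
  names(disc) <- features
  yd <- as.integer(factor(y))

  p <- length(features)
  V <- vapply(features, function(f) mi_value(disc[[f]], yd), numeric(1))
  pair <- matrix(NA_real_, p, p, dimnames = list(features, features))

  selected <- character(0)
  rows <- vector("list", p)
  for (step in seq_len(p)) {
    cand <- setdiff(features, selected)
    if (step == 1L) {
      W <- stats::setNames(rep(NA_real_, length(cand)), cand)
      score <- V[cand]
    } else {
      W <- vapply(cand, function(f) {
        for (s in selected) {
          if (is.na(pair[f, s])) {
            pair[f, s] <<- pair[s, f] <<- mi_value(disc[[f]], disc[[s]])
          }
        }
        mean(pair[f, selected])
      }, numeric(1))
      score <- ifelse(W > 0, V[cand] / W, ifelse(V[cand] > 0, Inf, 0))
      names(score) <- cand
    }
    ord <- order(-score, -V[cand], cand)
    best <- cand[ord[1]]
    rows[[step]] <- data.frame(
      rank = step, feature = best, score = unname(score[best]),
      relevance = unname(V[best]),
      redundancy = if (step == 1L) NA_real_ else unname(W[best]),
      stringsAsFactors = FALSE)
    selected <- c(selected, best)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ranked_features", "data.frame")
  out
}

#' Export a ranking as JSON (ordered names, scores, per-step V and W)
#' @param ranking A \code{ranked_features} data.frame.
#' @param path Output path.
#' @export
write_ranking <- function(ranking, path) {
  jsonlite::write_json(ranking, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
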