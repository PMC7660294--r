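test_that("equal-frequency binning honours bin counts and degenerate input", {
  expect_equal(discretize_column(rnorm(50), bins = 1), rep(1L, 50))
  codes <- discretize_column(1:8, bins = 4)
  expect_equal(as.integer(table(codes)), rep(2L, 4))  # four codes of size 2
  expect_equal(codes, rep(1:4, each = 2))
  expect_equal(discretize_column(rep(3.3, 20), bins = 10), rep(1L, 20))
  # ties merged: distinct codes never exceed distinct values
  v <- rep(c(1, 2), c(45, 5))
  expect_lte(length(unique(discretize_column(v, 10))), 2)
})

test_that("plug-in MI recovers entropy on identical variables, zero on constants", {
  x <- rep(1:2, each = 50)
  expect_equal(estimate_mutual_information(x, x)$value, log(2),
               tolerance = 1e-12)
  expect_equal(estimate_mutual_information(x, rep(1, 100))$value, 0)
  expect_error(estimate_mutual_information(1:4, 1:5), "length mismatch")
})

test_that("MI on a 2x2 joint table equals the brute-force double sum", {
  x <- rep(c(1, 1, 2, 2), c(30, 10, 10, 30))
  z <- rep(c(1, 2, 1, 2), c(30, 10, 10, 30))
  expect_equal(estimate_mutual_information(x, z)$value, bruteforce_mi(x, z),
               tolerance = 1e-12)
})

test_that("MI is symmetric and non-negative over random discrete pairs", {
  set.seed(404)
  for (i in 1:25) {
    x <- sample.int(sample(2:5, 1), 60, replace = TRUE)
    z <- sample.int(sample(2:5, 1), 60, replace = TRUE)
    a <- estimate_mutual_information(x, z)$value
    b <- estimate_mutual_information(z, x)$value
    expect_equal(a, b, tolerance = 1e-12)
    expect_gte(a, 0)
  }
})

test_that("coarsening a variable cannot raise its MI with the label", {
  set.seed(77)
  for (i in 1:10) {
    x <- sample.int(6, 80, replace = TRUE)
    y <- as.integer(x > 3) + sample(0:1, 80, replace = TRUE, prob = c(.8, .2))
    coarse <- (x + 1L) %/% 2L                       # deterministic merge 6 -> 3
    expect_gte(estimate_mutual_information(x, y)$value + 1e-12,
               estimate_mutual_information(coarse, y)$value)
  }
})

test_that("a single predictor ranks first with its relevance as the score", {
  m <- toy_matrix(cbind(c(1, 1, 9, 9)), c("impaired", "impaired",
                                          "healthy", "healthy"))
  r <- rank_features_mrmr(m, bins = 2, features = "tDuration_1")
  expect_equal(nrow(r), 1)
  expect_equal(r$feature, "tDuration_1")
  expect_equal(r$score, r$relevance)
  expect_equal(r$score, log(2), tolerance = 1e-12)
})

test_that("forward-addition ranking equals the exhaustive oracle on small instances", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(20:60, 1)
    p <- sample(3:5, 1)
    y <- sample.int(2, n, replace = TRUE)
    disc <- list()
    for (j in seq_len(p)) {
      # mix of label-linked and independent columns, already discrete
      disc[[sprintf("f%d", j)]] <- if (runif(1) < 0.5)
        ((y + sample.int(3, n, replace = TRUE)) %% 3L) + 1L
      else sample.int(4, n, replace = TRUE)
    }
    names(disc) <- sprintf("f%d", seq_len(p))
    m <- as.data.frame(disc)
    m$group <- c("healthy", "impaired")[y]
    m <- iadlscreen:::as_feature_matrix(
      cbind(data.frame(participant_id = sprintf("r%03d", seq_len(n)),
                       stringsAsFactors = FALSE), m),
      names(disc))
    got <- rank_features_mrmr(m, bins = 10)$feature
    want <- bruteforce_mrmr(disc, y)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("ranking is invariant to predictor column order", {
  ms <- small_cohort_matrices(55)
  tr <- impute_missing_durations(ms$train)
  r1 <- rank_features_mrmr(tr)$feature
  perm <- rev(predictors(tr))
  r2 <- rank_features_mrmr(tr, features = perm)$feature
  expect_equal(r1, r2)
})

test_that("a zero-variance label is a ranking error", {
  m <- toy_matrix(cbind(c(1, 2)), c("healthy", "healthy"))
  expect_error(rank_features_mrmr(m), "zero variance")
})
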