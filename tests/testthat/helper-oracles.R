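# Independent oracles and small fixture builders, kept deliberately naive
# and separate from the implementation paths they check.

# brute-force plug-in mutual information: explicit double loop over the
# joint table of two discrete vectors, in nats
bruteforce_mi <- function(x, z) {
  n <- length(x)
  xs <- unique(x); zs <- unique(z)
  total <- 0
  for (a in xs) {
    for (b in zs) {
      pj <- sum(x == a & z == b) / n
      if (pj > 0) {
        total <- total + pj * log(pj / ((sum(x == a) / n) * (sum(z == b) / n)))
      }
    }
  }
  total
}

# exhaustive forward-addition MRMR using bruteforce_mi, mirroring the
# quotient criterion and tie-break order (MIQ desc, V desc, name asc)
bruteforce_mrmr <- function(disc, y) {
  feats <- names(disc)
  V <- vapply(feats, function(f) bruteforce_mi(disc[[f]], y), numeric(1))
  selected <- character(0)
  for (step in seq_along(feats)) {
    cand <- setdiff(feats, selected)
    if (step == 1) {
      score <- V[cand]
    } else {
      W <- vapply(cand, function(f)
        mean(vapply(selected, function(s) bruteforce_mi(disc[[f]], disc[[s]]),
                    numeric(1))), numeric(1))
      score <- ifelse(W > 0, V[cand] / W, ifelse(V[cand] > 0, Inf, 0))
      names(score) <- cand
    }
    ord <- order(-score, -V[cand], cand)
    selected <- c(selected, cand[ord[1]])
  }
  selected
}

# a tiny handcrafted log: two tasks with known durations and tallied
# sensor activations
toy_log <- function() {
  lines <- c(
    "10:00:00.00000 TASK_1 BEGIN",
    "10:00:01.00000 M005 ON",
    "10:00:02.00000 M005 OFF",
    "10:00:03.00000 M005 ON",
    "10:00:04.00000 M005 OFF",
    "10:00:05.00000 M002 ON",
    "10:00:06.00000 M002 OFF",
    "10:01:00.00000 TASK_1 END",
    "10:01:40.00000 TASK_3 BEGIN",
    "10:01:50.00000 M005 ON",
    "10:01:55.00000 M005 OFF",
    "10:02:10.00000 M030 ON",
    "10:02:15.00000 M030 OFF",
    "10:03:20.00000 TASK_3 END")
  parse_event_log(lines, participant_id = "toy", category_code = 1L)
}

# feature matrix built directly from numbers (bypasses log parsing) for
# preprocessing/balancing/modeling tests
toy_matrix <- function(durations, group, extra = NULL) {
  n <- length(group)
  m <- as.data.frame(durations)
  names(m) <- sprintf("tDuration_%d", seq_len(ncol(m)))
  for (k in seq_len(8 - ncol(durations))) m[[sprintf("tDuration_%d", ncol(durations) + k)]] <- 1
  m <- m[, sprintf("tDuration_%d", 1:8)]
  if (!is.null(extra)) m <- cbind(m, extra)
  m$TotalTime <- rowSums(m[, sprintf("tDuration_%d", 1:8)])
  m$TaskScore <- rowSums(m[, sprintf("tDuration_%d", 1:8)] > 0)
  m$Total_sEvents <- 0
  out <- cbind(data.frame(participant_id = sprintf("p%02d", seq_len(n)),
                          group = group, stringsAsFactors = FALSE), m)
  manifest <- setdiff(names(m), c("participant_id", "group"))
  iadlscreen:::as_feature_matrix(out, manifest)
}

# a 2-class gaussian-cloud matrix for balancing/modeling tests
cloud_matrix <- function(n_min = 12, n_maj = 30, sep = 3, seed = 1, p = 2) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_min * p), n_min) + sep,
             matrix(rnorm(n_maj * p), n_maj))
  df <- as.data.frame(X)
  names(df) <- sprintf("f%d", seq_len(p))
  out <- cbind(data.frame(
    participant_id = sprintf("c%03d", seq_len(n_min + n_maj)),
    group = rep(c("impaired", "healthy"), c(n_min, n_maj)),
    stringsAsFactors = FALSE), df)
  iadlscreen:::as_feature_matrix(out, names(df))
}

# cohort params with class signal ONLY in task durations: completion
# certain, identical per-sensor expected counts (rate scaled down by the
# duration stretch), no transition-rate contrast
planted_healthy <- function() {
  behaviour_params(completion_prob = 1,
                   duration_meanlog = log(c(300, 240, 300, 420, 240, 300, 180, 240)),
                   duration_sdlog = 0.3, event_rate = 0.02,
                   transition_multiplier = 1)
}

planted_impaired <- function() {
  behaviour_params(completion_prob = 1,
                   duration_meanlog = log(c(300, 240, 300, 420, 240, 300, 180, 240)) + log(1.6),
                   duration_sdlog = 0.3, event_rate = 0.02 / 1.6,
                   transition_multiplier = 1)
}

# quick labelled train/test matrices from a seeded synthetic cohort
small_cohort_matrices <- function(seed, n_tr_imp = 20, n_tr_hea = 40,
                                  n_te_imp = 8, n_te_hea = 12) {
  co <- generate_cohort(cohort_config(n_tr_imp, n_tr_hea, n_te_imp, n_te_hea,
                                      seed = seed))
  fm <- build_feature_matrix(co$logs, co$labels)
  sp <- co$labels$split[match(fm$participant_id, co$labels$participant_id)]
  list(train = fm[sp == "train", , drop = FALSE],
       test = fm[sp == "test", , drop = FALSE])
}
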