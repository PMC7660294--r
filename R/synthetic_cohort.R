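#' Class-conditional behaviour parameters for the cohort generator
#'
#' Describes how one cognitive group behaves during a scripted eight-task
#' IADL session: the probability of completing each task, the lognormal
#' duration of a completed task, the Poisson firing rate of task-relevant
#' motion sensors, and a rate multiplier for transition sensors (corridor /
#' doorway sensors whose extra firings proxy wandering and restlessness).
#'
#' @param completion_prob Per-task completion probability, length 1 or 8.
#' @param duration_meanlog,duration_sdlog Lognormal location/scale of task
#'   duration in seconds, length 1 or 8.
#' @param event_rate Poisson ON/OFF-pair rate per task-relevant sensor,
#'   events per second, length 1 or 8.
#' @param transition_multiplier Rate multiplier (>= 1) applied to transition
#'   sensors during every task window.
#' @return Object of class \code{"behaviour_params"} with all fields
#'   recycled to length 8.
#' @export
behaviour_params <- function(completion_prob, duration_meanlog,
                             duration_sdlog, event_rate,
                             transition_multiplier = 1) {
  p <- rep_len(completion_prob, 8L)
  mu <- rep_len(duration_meanlog, 8L)
  sg <- rep_len(duration_sdlog, 8L)
  lam <- rep_len(event_rate, 8L)
  stopifnot(all(p >= 0 & p <= 1), all(sg > 0), all(lam > 0),
            transition_multiplier >= 1)
  structure(list(completion_prob = p, duration_meanlog = mu,
                 duration_sdlog = sg, event_rate = lam,
                 transition_multiplier = transition_multiplier),
            class = "behaviour_params")
}

# Baseline healthy task durations (seconds): sweep, medicines, birthday
# card, DVD, water plants, phone, soup, outfit.
healthy_task_durations <- c(300, 240, 300, 420, 240, 300, 180, 240)

#' @rdname behaviour_params
#' @export
healthy_behaviour_params <- function() {
  behaviour_params(completion_prob = 0.97,
                   duration_meanlog = log(healthy_task_durations),
                   duration_sdlog = 0.30,
                   event_rate = 0.04,
                   transition_multiplier = 1)
}

#' @rdname behaviour_params
#' @export
impaired_behaviour_params <- function() {
  # durations stretched 1.6x, event rate scaled down by the same factor so
  # mean per-sensor counts stay comparable; doubled transition-sensor rate
  # as the wandering proxy
  behaviour_params(completion_prob = 0.75,
                   duration_meanlog = log(healthy_task_durations) + log(1.6),
                   duration_sdlog = 0.45,
                   event_rate = 0.04 / 1.6,
                   transition_multiplier = 2)
}

#' Default smart-home motion-sensor inventory
#'
#' 51 motion sensors M001..M051.  M027..M050 serve the upper floor and are
#' excluded from the feature matrix; the ground floor keeps M001..M026 plus
#' M051 (27 sensors).  Corridor/doorway sensors M001, M015, M016, M018,
#' M021, M023 are transition sensors.  Each task is assigned a small subset
#' of the non-transition ground-floor sensors; transition sensors are active
#' during every task window.
#'
#' @return List with \code{sensors}, \code{retained}, \code{transition},
#'   and \code{task_map} (list of 8 sensor-id vectors).
#' @export
default_sensor_inventory <- function() {
  sensors <- sprintf("M%03d", 1:51)
  retained <- c(sprintf("M%03d", 1:26), "M051")
  transition <- c("M001", "M015", "M016", "M018", "M021", "M023")
  pool <- setdiff(retained, transition)             # 21 task sensors
  task_map <- split(pool, rep_len(1:8, length(pool)))
  names(task_map) <- as.character(1:8)
  list(sensors = sensors, retained = retained,
       transition = transition, task_map = task_map)
}

# deterministic per-unit seed stream from a master seed (kept below 2^31)
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

round5 <- function(x) round(x, 5)  # match the log dialect's time precision

#' Generate one synthetic participant log
#'
#' Tasks are attempted in order 1..8.  Each task is completed with its
#' Bernoulli probability; a completed task emits a BEGIN marker, paired
#' ON/OFF motion events at the class's Poisson rate on the task's sensor
#' subset (transition sensors at the multiplied rate), and an END marker
#' after a lognormal duration.  Skipped tasks emit nothing.  Inter-task
#' idle gaps are Uniform(5, 30) seconds.
#'
#' @param params A \code{\link{behaviour_params}}.
#' @param inventory A sensor inventory, see
#'   \code{\link{default_sensor_inventory}}.
#' @param participant_id,category_code Recorded on the log.
#' @param seed Optional integer; when given the log is a pure function of it.
#' @return A \code{\link{participant_log}}.
#' @export
generate_participant_log <- function(params, inventory = default_sensor_inventory(),
                                     participant_id = "sim", category_code = NA_integer_,
                                     seed = NULL) {
  gen <- function() {
    t <- 0
    ev_time <- numeric(0); ev_id <- character(0); ev_state <- character(0)
    mk_task <- integer(0); mk_boundary <- character(0); mk_time <- numeric(0)
    for (k in 1:8) {
      t <- t + stats::runif(1, 5, 30)
      if (stats::runif(1) > params$completion_prob[k]) next
      dur <- stats::rlnorm(1, params$duration_meanlog[k], params$duration_sdlog[k])
      dur <- max(dur, 1)
      task_sensors <- inventory$task_map[[as.character(k)]]
      rates <- c(rep(params$event_rate[k], length(task_sensors)),
                 rep(params$event_rate[k] * params$transition_multiplier,
                     length(inventory$transition)))
      ids <- c(task_sensors, inventory$transition)
      for (j in seq_along(ids)) {
        n_pair <- stats::rpois(1, rates[j] * dur)
        if (n_pair == 0) next
        on <- sort(stats::runif(n_pair, t, t + dur * 0.99))
        off <- pmin(on + stats::runif(n_pair, 0.5, 3), t + dur)
        ev_time <- c(ev_time, on, off)
        ev_id <- c(ev_id, rep(ids[j], 2 * n_pair))
        ev_state <- c(ev_state, rep("ON", n_pair), rep("OFF", n_pair))
      }
      mk_task <- c(mk_task, k, k)
      mk_boundary <- c(mk_boundary, "BEGIN", "END")
      mk_time <- c(mk_time, t, t + dur)
      t <- t + dur
    }
    origin <- if (length(ev_time) || length(mk_time))
      min(c(ev_time, mk_time)) else 0
    events <- data.frame(time = round5(ev_time - origin), sensor_id = ev_id,
                         state = ev_state, stringsAsFactors = FALSE)
    markers <- data.frame(task = mk_task, boundary = mk_boundary,
                          time = round5(mk_time - origin), stringsAsFactors = FALSE)
    markers <- markers[order(markers$time), , drop = FALSE]
    participant_log(participant_id, category_code, events, markers)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Cohort configuration for the synthetic generator
#'
#' Defaults emulate the study cohort: 56 impaired / 194 healthy training
#' participants and 20 / 34 test participants.
#'
#' @param n_train_impaired,n_train_healthy,n_test_impaired,n_test_healthy
#'   Per-class, per-split participant counts.
#' @param params_impaired,params_healthy \code{\link{behaviour_params}}.
#' @param inventory Sensor inventory.
#' @param seed Master seed; every participant's log is derived from it.
#' @return Object of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_train_impaired = 56, n_train_healthy = 194,
                          n_test_impaired = 20, n_test_healthy = 34,
                          params_impaired = impaired_behaviour_params(),
                          params_healthy = healthy_behaviour_params(),
                          inventory = default_sensor_inventory(),
                          seed = 1L) {
  stopifnot(n_train_impaired >= 0, n_train_healthy >= 0,
            n_test_impaired >= 0, n_test_healthy >= 0)
  structure(list(n_train_impaired = n_train_impaired,
                 n_train_healthy = n_train_healthy,
                 n_test_impaired = n_test_impaired,
                 n_test_healthy = n_test_healthy,
                 params_impaired = params_impaired,
                 params_healthy = params_healthy,
                 inventory = inventory, seed = as.integer(seed)),
            class = "cohort_config")
}

# impaired codes cycle dementia/MCI; healthy codes cycle the five healthy
# subgroups, each with its age band
impaired_codes <- c(1L, 2L)
healthy_codes <- 3:7
age_band_for_code <- c("75+", "60-74", "45-59", "60-74", "75+", "18-44", "18-44",
                       NA, NA, NA)

#' Generate a labelled synthetic cohort
#'
#' @param config A \code{\link{cohort_config}}.
#' @return List with \code{logs} (list of \code{participant_log}) and
#'   \code{labels} (data.frame: participant_id, category_code, age_group,
#'   group, split).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  plan <- rbind(
    data.frame(split = "train", group = "impaired",
               n = config$n_train_impaired, stringsAsFactors = FALSE),
    data.frame(split = "train", group = "healthy",
               n = config$n_train_healthy, stringsAsFactors = FALSE),
    data.frame(split = "test", group = "impaired",
               n = config$n_test_impaired, stringsAsFactors = FALSE),
    data.frame(split = "test", group = "healthy",
               n = config$n_test_healthy, stringsAsFactors = FALSE))
  logs <- list()
  labels <- NULL
  idx <- 0L
  for (r in seq_len(nrow(plan))) {
    n <- plan$n[r]
    if (n == 0) next
    grp <- plan$group[r]
    params <- if (grp == "impaired") config$params_impaired else config$params_healthy
    codes <- if (grp == "impaired") impaired_codes else healthy_codes
    for (i in seq_len(n)) {
      idx <- idx + 1L
      pid <- sprintf("P%04d", idx)
      code <- codes[(i - 1L) %% length(codes) + 1L]
      logs[[pid]] <- generate_participant_log(
        params, config$inventory, participant_id = pid, category_code = code,
        seed = derive_seed(config$seed, idx))
      labels <- rbind(labels, data.frame(
        participant_id = pid, category_code = code,
        age_group = age_band_for_code[code], group = grp,
        split = plan$split[r], stringsAsFactors = FALSE))
    }
  }
  if (is.null(labels))
    labels <- data.frame(participant_id = character(0),
                         category_code = integer(0), age_group = character(0),
                         group = character(0), split = character(0),
                         stringsAsFactors = FALSE)
  list(logs = logs, labels = labels)
}

#' Write a cohort to disk as one log file per participant plus a labels CSV
#'
#' @param cohort Result of \code{\link{generate_cohort}}.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(cohort$logs))
    write_event_log(cohort$logs[[pid]], file.path(dir, paste0(pid, ".txt")))
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  invisible(dir)
}
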