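#' Log-file dialect for CASAS-style sensor event logs
#'
#' Describes how raw log lines are interpreted: how clock times are written
#' and which lines are task-boundary annotations rather than sensor events.
#' The defaults match whitespace-separated lines of the form
#' \code{"09:07:02.27948 M015 OFF"}, with task markers written as
#' \code{"<clock-time> TASK_<k> BEGIN|END"}.  Real annotated archives use
#' observer-specific marker tokens, so the marker pattern is configurable:
#' it must be a regular expression whose first capture group is the task
#' number.
#'
#' @param marker_pattern Regular expression matched against the second token
#'   of a line; first capture group must yield the integer task index.
#' @param begin_token,end_token State tokens that mark a task beginning/end.
#' @return An object of class \code{"log_dialect"}.
#' @export
log_dialect <- function(marker_pattern = "^TASK_([0-9]+)$",
                        begin_token = "BEGIN", end_token = "END") {
  structure(list(marker_pattern = marker_pattern,
                 begin_token = begin_token,
                 end_token = end_token),
            class = "log_dialect")
}

# "09:07:02.27948" -> seconds since midnight (numeric)
parse_clock_time <- function(tok) {
  parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L) return(NA_real_)
  v <- suppressWarnings(as.numeric(parts))
  if (anyNA(v) || v[1] < 0 || v[2] < 0 || v[3] < 0) return(NA_real_)
  v[1] * 3600 + v[2] * 60 + v[3]
}

format_clock_time <- function(sec) {
  h <- floor(sec / 3600) %% 24
  m <- floor((sec %% 3600) / 60)
  s <- sec %% 60
  sprintf("%02d:%02d:%08.5f", as.integer(h), as.integer(m), s)
}

#' Construct a participant log
#'
#' A participant log holds the time-ordered sensor events of one smart-home
#' session, the begin/end annotations of the eight scripted IADL tasks, the
#' participant identifier and the 10-way cognitive category code.
#'
#' @param participant_id Character scalar.
#' @param category_code Integer in 1..10, or NA when unlabeled.
#' @param events data.frame with columns \code{time} (seconds, numeric),
#'   \code{sensor_id}, \code{state} (character).
#' @param markers data.frame with columns \code{task} (integer 1..8),
#'   \code{boundary} ("BEGIN"/"END"), \code{time} (seconds).
#' @return An object of class \code{"participant_log"}.
#' @export
participant_log <- function(participant_id, category_code = NA_integer_,
                            events = empty_events(), markers = empty_markers()) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  if (!is.na(category_code) && !(category_code %in% 1:10))
    stop("category_code must be in 1..10, got ", category_code)
  events <- events[order(events$time), , drop = FALSE]  # stable sort
  rownames(events) <- NULL
  rownames(markers) <- NULL
  if (nrow(events) && any(events$time < 0))
    stop("event times must be non-negative")
  if (nrow(markers)) {
    if (any(duplicated(markers[, c("task", "boundary")])))
      stop("at most one BEGIN and one END per task")
    for (k in unique(markers$task)) {
      b <- markers$time[markers$task == k & markers$boundary == "BEGIN"]
      e <- markers$time[markers$task == k & markers$boundary == "END"]
      if (length(b) && length(e) && e < b)
        stop("task ", k, ": END precedes BEGIN")
    }
  }
  structure(list(participant_id = participant_id,
                 category_code = as.integer(category_code),
                 events = events, markers = markers),
            class = "participant_log")
}

empty_events <- function() {
  data.frame(time = numeric(0), sensor_id = character(0),
             state = character(0), stringsAsFactors = FALSE)
}

empty_markers <- function() {
  data.frame(task = integer(0), boundary = character(0),
             time = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.participant_log <- function(x, ...) {
  cat("<participant_log> ", x$participant_id,
      " | category ", ifelse(is.na(x$category_code), "?", x$category_code),
      " | ", nrow(x$events), " events, ", nrow(x$markers), " markers\n", sep = "")
  invisible(x)
}

#' Parse a CASAS-dialect sensor event log
#'
#' Reads whitespace-separated lines \code{<clock-time> <sensor_id> <state>}.
#' Lines whose second token matches the dialect's marker pattern are task
#' boundaries; all others are sensor events.  Clock times are converted to
#' seconds relative to the first line of the session; a backwards clock jump
#' larger than 12 h is treated as a midnight wrap and 24 h is added to all
#' subsequent times.  Events are stably sorted by time, so minor clock
#' jitter is tolerated rather than rejected.
#'
#' @param x Path to a log file, or a character vector of lines.
#' @param dialect A \code{\link{log_dialect}}.
#' @param participant_id Identifier recorded on the returned log.
#' @param category_code Optional cognitive category code 1..10.
#' @return A \code{\link{participant_log}}.
#' @export
parse_event_log <- function(x, dialect = log_dialect(),
                            participant_id = "unknown",
                            category_code = NA_integer_) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0L)
    return(participant_log(participant_id, category_code))

  time <- numeric(n); id <- character(n); state <- character(n)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(toks) != 3L)
      stop("line ", i, ": expected 3 fields, got ", length(toks))
    t <- parse_clock_time(toks[1])
    if (is.na(t)) stop("line ", i, ": unparseable time '", toks[1], "'")
    if (!nzchar(toks[2])) stop("line ", i, ": empty sensor token")
    time[i] <- t; id[i] <- toks[2]; state[i] <- toks[3]
  }

  # midnight wrap: a backwards jump > 12 h in an append-only log; smaller
  # backwards jumps are clock jitter and handled by the stable sort
  raw <- time
  day <- 0
  for (i in seq_len(n)[-1]) {
    if (raw[i] < raw[i - 1] - 43200) day <- day + 1
    time[i] <- raw[i] + day * 86400
  }
  # rebase to the session start; round to the dialect's 1e-5 s precision so
  # write -> parse round trips are exact
  time <- round(time - min(time), 5)

  is_marker <- grepl(dialect$marker_pattern, id)
  mk <- which(is_marker & state %in% c(dialect$begin_token, dialect$end_token))
  ev <- setdiff(seq_len(n), mk)

  markers <- empty_markers()
  if (length(mk)) {
    task <- as.integer(sub(dialect$marker_pattern, "\\1", id[mk]))
    boundary <- ifelse(state[mk] == dialect$begin_token, "BEGIN", "END")
    markers <- data.frame(task = task, boundary = boundary, time = time[mk],
                          stringsAsFactors = FALSE)
    markers <- markers[order(markers$time), , drop = FALSE]
  }
  events <- data.frame(time = time[ev], sensor_id = id[ev], state = state[ev],
                       stringsAsFactors = FALSE)
  participant_log(participant_id, category_code, events, markers)
}

#' Write a participant log back to its text dialect
#'
#' Emits one line per event and marker, in time order, using the same
#' whitespace-separated clock-time dialect the parser reads, so that
#' \code{parse_event_log(write_event_log(x))} reproduces the events and
#' markers of \code{x}.  Relative times are rendered as clock times starting
#' at 00:00:00.
#'
#' @param log A \code{\link{participant_log}}.
#' @param path Optional file path; when NULL the lines are returned.
#' @param dialect A \code{\link{log_dialect}}.
#' @return Character vector of lines (invisibly when written to file).
#' @export
write_event_log <- function(log, path = NULL, dialect = log_dialect()) {
  stopifnot(inherits(log, "participant_log"))
  ev <- log$events
  mk <- log$markers
  rows <- data.frame(
    time = c(ev$time, mk$time),
    id = c(ev$sensor_id,
           if (nrow(mk)) sprintf("TASK_%d", mk$task) else character(0)),
    state = c(ev$state,
              if (nrow(mk)) ifelse(mk$boundary == "BEGIN",
                                   dialect$begin_token, dialect$end_token)
              else character(0)),
    stringsAsFactors = FALSE)
  rows <- rows[order(rows$time), , drop = FALSE]
  lines <- sprintf("%s %s %s", format_clock_time(rows$time), rows$id, rows$state)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Map a 10-way cognitive category code to its parent group
#'
#' The cohort's ten cognitive-state categories collapse into three parent
#' groups: dementia and MCI form the impaired group; the five healthy
#' subgroups (middle age 45-59, young-old 60-74, old 75+, younger adults,
#' younger adults with English as a second language) form the healthy group;
#' other-medical, at-risk and diagnosis-not-available records are unknown
#' and are discarded before modeling.
#'
#' @param category_code Integer vector with values in 1..10.
#' @return Character vector with values "impaired", "healthy" or "unknown".
#' @export
map_cognitive_category <- function(category_code) {
  code <- as.integer(category_code)
  if (anyNA(code) || any(code < 1L | code > 10L))
    stop("category codes must be integers in 1..10")
  out <- character(length(code))
  out[code %in% 1:2] <- "impaired"
  out[code %in% 3:7] <- "healthy"
  out[code %in% 8:10] <- "unknown"
  out
}

#' Read a participant label table
#'
#' @param path CSV with columns participant_id, category_code and optionally
#'   age_group (a band such as "45-59" or "75+").
#' @return data.frame with an added \code{group} column from
#'   \code{\link{map_cognitive_category}}.
#' @export
read_label_table <- function(path) {
  lab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("participant_id", "category_code") %in% names(lab)))
    stop("label table needs columns participant_id, category_code")
  lab$group <- map_cognitive_category(lab$category_code)
  lab
}

# "45-59" -> 52, "75+" -> 80, "60-74" -> 67
age_band_midpoint <- function(band) {
  vapply(band, function(b) {
    if (grepl("^\\s*([0-9]+)\\s*-\\s*([0-9]+)\\s*$", b)) {
      lo <- as.numeric(sub("^\\s*([0-9]+)\\s*-.*$", "\\1", b))
      hi <- as.numeric(sub("^.*-\\s*([0-9]+)\\s*$", "\\1", b))
      (lo + hi) / 2
    } else if (grepl("^\\s*([0-9]+)\\s*\\+\\s*$", b)) {
      as.numeric(sub("\\+", "", trimws(b))) + 5
    } else NA_real_
  }, numeric(1), USE.NAMES = FALSE)
}
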