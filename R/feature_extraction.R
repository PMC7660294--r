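#' Default retained motion-sensor set
#'
#' Ground-floor motion sensors M001..M026 plus M051; the upper-floor block
#' M027..M050 is excluded from the feature matrix.  27 sensors in total.
#'
#' @return Character vector of sensor ids.
#' @export
default_retained_sensors <- function() {
  c(sprintf("M%03d", 1:26), "M051")
}

#' Predictor-column manifest of the feature matrix
#'
#' @param retained_sensors Sensor ids whose activation counts are columns.
#' @param include_age Add the optional Age predictor (age-band midpoint).
#' @return Character vector of predictor names: 8 task durations, one
#'   \code{s<SensorID>} count per retained sensor, TotalTime, TaskScore,
#'   Total_sEvents (38 with the default sensor set; 39 with Age).
#' @export
feature_manifest <- function(retained_sensors = default_retained_sensors(),
                             include_age = FALSE) {
  c(sprintf("tDuration_%d", 1:8),
    paste0("s", retained_sensors),
    "TotalTime", "TaskScore", "Total_sEvents",
    if (include_age) "Age")
}

duration_cols <- function() sprintf("tDuration_%d", 1:8)

#' Extract the feature vector of one participant log
#'
#' Events are first trimmed to the span from the first BEGIN to the last
#' END marker.  Task duration is END minus BEGIN when both markers exist
#' and 0 seconds otherwise (a task not done).  Sensor features count ON
#' transitions of each retained sensor within the trimmed span: a full
#' activate/deactivate cycle counts once.  Derived features: TotalTime is
#' the sum of the eight durations, TaskScore the number of completed tasks,
#' Total_sEvents the sum of the retained sensor counts.
#'
#' @param log A \code{\link{participant_log}}.
#' @param retained_sensors Sensor ids to count.
#' @return Named numeric vector following \code{\link{feature_manifest}}
#'   (without Age).
#' @export
extract_features <- function(log, retained_sensors = default_retained_sensors()) {
  stopifnot(inherits(log, "participant_log"), length(retained_sensors) > 0)
  mk <- log$markers
  dur <- stats::setNames(numeric(8), duration_cols())
  for (k in 1:8) {
    b <- mk$time[mk$task == k & mk$boundary == "BEGIN"]
    e <- mk$time[mk$task == k & mk$boundary == "END"]
    if (length(b) == 1L && length(e) == 1L) {
      if (e < b) stop("task ", k, ": END precedes BEGIN")
      dur[k] <- e - b
    }
  }

  counts <- stats::setNames(numeric(length(retained_sensors)),
                            paste0("s", retained_sensors))
  begins <- mk$time[mk$boundary == "BEGIN"]
  ends <- mk$time[mk$boundary == "END"]
  if (length(begins) && length(ends)) {
    span <- c(min(begins), max(ends))
    ev <- log$events
    on <- ev[ev$state == "ON" & ev$time >= span[1] & ev$time <= span[2] &
               ev$sensor_id %in% retained_sensors, , drop = FALSE]
    if (nrow(on)) {
      tab <- table(on$sensor_id)
      counts[paste0("s", names(tab))] <- as.numeric(tab)
    }
  }

  c(dur, counts,
    TotalTime = sum(dur), TaskScore = sum(dur > 0),
    Total_sEvents = sum(counts))
}

#' Build the feature matrix of a cohort
#'
#' One row per participant log, columns per
#' \code{\link{feature_manifest}}, plus \code{participant_id} and the
#' parent cognitive \code{group} taken from the label table (or from the
#' log's own category code when no table is given).
#'
#' @param logs List of \code{\link{participant_log}} objects.
#' @param labels Optional data.frame with participant_id, category_code and
#'   optionally age_group columns (see \code{\link{read_label_table}}).
#' @param retained_sensors Sensor ids to count.
#' @param include_age Add the Age predictor from the label table's age band
#'   midpoint.
#' @return data.frame of class \code{"feature_matrix"}; the predictor
#'   manifest is stored in \code{attr(, "predictors")}.
#' @export
build_feature_matrix <- function(logs, labels = NULL,
                                 retained_sensors = default_retained_sensors(),
                                 include_age = FALSE) {
  ids <- vapply(logs, function(l) l$participant_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate participant_id: ", ids[duplicated(ids)][1])
  manifest <- feature_manifest(retained_sensors, include_age)

  rows <- lapply(logs, extract_features, retained_sensors = retained_sensors)
  mat <- if (length(rows)) as.data.frame(do.call(rbind, rows)) else
    as.data.frame(matrix(numeric(0), nrow = 0,
                         ncol = length(feature_manifest(retained_sensors)),
                         dimnames = list(NULL, feature_manifest(retained_sensors))))

  group <- character(length(logs))
  age <- rep(NA_real_, length(logs))
  for (i in seq_along(logs)) {
    code <- logs[[i]]$category_code
    band <- NA_character_
    if (!is.null(labels)) {
      j <- match(ids[i], labels$participant_id)
      if (is.na(j)) stop("no label for participant ", ids[i])
      code <- labels$category_code[j]
      if ("age_group" %in% names(labels)) band <- labels$age_group[j]
    }
    group[i] <- if (is.na(code)) NA_character_ else map_cognitive_category(code)
    if (include_age) {
      if (is.na(band)) stop("include_age = TRUE needs an age_group for ", ids[i])
      age[i] <- age_band_midpoint(band)
    }
  }
  if (include_age) mat$Age <- age

  out <- cbind(data.frame(participant_id = unname(ids), group = group,
                          stringsAsFactors = FALSE),
               mat)
  rownames(out) <- NULL
  as_feature_matrix(out, manifest)
}

as_feature_matrix <- function(df, manifest) {
  missing <- setdiff(manifest, names(df))
  if (length(missing))
    stop("feature matrix lacks columns: ", paste(missing, collapse = ", "))
  attr(df, "predictors") <- manifest
  class(df) <- c("feature_matrix", "data.frame")
  df
}

#' Predictor manifest of a feature matrix
#' @param m A feature matrix.
#' @export
predictors <- function(m) attr(m, "predictors")

#' @export
`[.feature_matrix` <- function(x, ...) {
  manifest <- attr(x, "predictors")
  out <- NextMethod()
  if (is.data.frame(out) && all(manifest %in% names(out))) {
    attr(out, "predictors") <- manifest
    class(out) <- unique(c("feature_matrix", class(out)))
  }
  out
}

#' Write / read a feature matrix as CSV with a JSON provenance sidecar
#'
#' @param m A feature matrix.
#' @param path CSV path; the sidecar is written next to it as
#'   \code{<path>.meta.json}.
#' @param extra Named list merged into the sidecar.
#' @export
write_feature_matrix <- function(m, path, extra = list()) {
  utils::write.csv(m, path, row.names = FALSE)
  meta <- c(list(predictors = predictors(m), n_rows = nrow(m),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            extra)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  manifest <- if (file.exists(meta_path))
    unlist(jsonlite::read_json(meta_path)$predictors) else
      setdiff(names(df), c("participant_id", "group"))
  as_feature_matrix(df, manifest)
}
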