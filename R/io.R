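# Data model and file I/O for diary-study datasets.
#
# A dataset has three tables:
#   events(participant_id, day_index, event_index, title, description,
#          regularity, happy, positive, sad, negative, excited, calm, afraid)
#   recalls(participant_id, day_index, event_index, vividness, recall_text,
#           test_arm)
#   days(participant_id, day_index, day_positivity)   [optional]
#
# Missing diary days are simply absent rows; they are never imputed. Day and
# event indices are 1-based, mirroring the diary protocol.

EVENTS_COLUMNS  <- c("participant_id", "day_index", "event_index", "title",
                     "description", "regularity", EMOTION_NAMES)
RECALLS_COLUMNS <- c("participant_id", "day_index", "event_index", "vividness",
                     "recall_text", "test_arm")
DAYS_COLUMNS    <- c("participant_id", "day_index", "day_positivity")
TEST_ARMS       <- c("event_recall", "temporal_pair")

#' Assemble and validate a diary dataset
#'
#' Builds a `diary_dataset` from the three component tables, enforcing every
#' structural invariant of the data model: regularity labels in
#' `new/periodic/routine`, integer emotion ratings in 1--5, unique
#' (participant, day, event) keys, vividness in 1--5 for every tested event,
#' recall text present exactly for the `event_recall` arm, at most one
#' `event_recall` row per participant-day, and referential integrity of every
#' recall row against the event table. Free-text fields are
#' whitespace-normalized (see [normalize_text()]); case is preserved.
#'
#' If a `days` table is supplied, a logical `has_new_event` column is derived:
#' `TRUE` when at least one event reported on that participant-day is labeled
#' `new`.
#'
#' @param events data.frame of diary events (one row per reported event).
#' @param recalls data.frame of delayed-memory-test outcomes, or `NULL`.
#' @param days data.frame of day-level mood ratings, or `NULL`.
#' @return An object of class `diary_dataset`: a list with elements `events`,
#'   `recalls`, `days`.
#' @export
as_diary_dataset <- function(events, recalls = NULL, days = NULL) {
  events <- validate_events(events)
  if (!is.null(recalls)) recalls <- validate_recalls(recalls, events)
  if (!is.null(days)) days <- validate_days(days, events)
  structure(list(events = events, recalls = recalls, days = days),
            class = "diary_dataset")
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    nd_schema_error("%s table is missing required column(s): %s",
                    what, paste(missing, collapse = ", "))
  }
  df[, required, drop = FALSE]
}

validate_events <- function(events) {
  events <- check_columns(as.data.frame(events), EVENTS_COLUMNS, "events")
  n <- nrow(events)
  events$participant_id <- as.character(events$participant_id)
  events$title <- normalize_text(events$title)
  events$description <- normalize_text(events$description)
  events$regularity <- as.character(events$regularity)

  bad <- which(is.na(events$participant_id) | events$participant_id == "")
  if (length(bad)) nd_validation_error("events row %d: empty participant_id", bad[1])
  for (col in c("day_index", "event_index")) {
    v <- events[[col]]
    bad <- which(!is_whole(v) | v < 1L)
    if (length(bad)) {
      nd_validation_error("events row %d: %s must be an integer >= 1 (got %s)",
                          bad[1], col, v[bad[1]])
    }
    events[[col]] <- as.integer(v)
  }
  bad <- which(events$event_index > 3L)
  if (length(bad)) {
    nd_validation_error("events row %d: event_index must be in {1,2,3} (got %d)",
                        bad[1], events$event_index[bad[1]])
  }
  bad <- which(is.na(events$description) | events$description == "")
  if (length(bad)) nd_validation_error("events row %d: empty description", bad[1])
  bad <- which(!(events$regularity %in% REGULARITY_LEVELS))
  if (length(bad)) {
    nd_validation_error("events row %d: unknown regularity label '%s'",
                        bad[1], events$regularity[bad[1]])
  }
  for (col in EMOTION_NAMES) {
    v <- events[[col]]
    bad <- which(!is_whole(v) | v < 1 | v > 5)
    if (length(bad)) {
      nd_validation_error("events row %d: emotion rating '%s' must be an integer in [1,5] (got %s)",
                          bad[1], col, v[bad[1]])
    }
    events[[col]] <- as.integer(v)
  }
  key <- event_key(events$participant_id, events$day_index, events$event_index)
  dup <- which(duplicated(key))
  if (length(dup)) {
    nd_validation_error("events row %d: duplicate (participant_id, day_index, event_index) key '%s'",
                        dup[1], key[dup[1]])
  }
  rownames(events) <- NULL
  events
}

validate_recalls <- function(recalls, events) {
  recalls <- check_columns(as.data.frame(recalls), RECALLS_COLUMNS, "recalls")
  recalls$participant_id <- as.character(recalls$participant_id)
  recalls$recall_text <- normalize_text(recalls$recall_text)
  recalls$recall_text[recalls$recall_text == ""] <- NA_character_
  recalls$test_arm <- as.character(recalls$test_arm)

  for (col in c("day_index", "event_index")) {
    v <- recalls[[col]]
    bad <- which(!is_whole(v) | v < 1L)
    if (length(bad)) {
      nd_validation_error("recalls row %d: %s must be an integer >= 1", bad[1], col)
    }
    recalls[[col]] <- as.integer(v)
  }
  bad <- which(!is_whole(recalls$vividness) | recalls$vividness < 1 | recalls$vividness > 5)
  if (length(bad)) {
    nd_validation_error("recalls row %d: vividness must be an integer in [1,5] (got %s)",
                        bad[1], recalls$vividness[bad[1]])
  }
  recalls$vividness <- as.integer(recalls$vividness)
  bad <- which(!(recalls$test_arm %in% TEST_ARMS))
  if (length(bad)) {
    nd_validation_error("recalls row %d: unknown test_arm '%s'",
                        bad[1], recalls$test_arm[bad[1]])
  }
  # recall text present iff the event was in the free-recall arm
  bad <- which(recalls$test_arm == "event_recall" & is.na(recalls$recall_text))
  if (length(bad)) {
    nd_validation_error("recalls row %d: event_recall arm requires recall_text", bad[1])
  }
  bad <- which(recalls$test_arm == "temporal_pair" & !is.na(recalls$recall_text))
  if (length(bad)) {
    nd_validation_error("recalls row %d: temporal_pair arm must not carry recall_text", bad[1])
  }

  ekey <- event_key(events$participant_id, events$day_index, events$event_index)
  rkey <- event_key(recalls$participant_id, recalls$day_index, recalls$event_index)
  dup <- which(duplicated(rkey))
  if (length(dup)) {
    nd_validation_error("recalls row %d: duplicate event key '%s'", dup[1], rkey[dup[1]])
  }
  dangling <- which(!(rkey %in% ekey))
  if (length(dangling)) {
    nd_referential_error("recalls row %d: event key '%s' does not match any event",
                         dangling[1], rkey[dangling[1]])
  }
  # at most one free-recall event per participant-day
  er <- recalls[recalls$test_arm == "event_recall", , drop = FALSE]
  pd <- paste(er$participant_id, er$day_index, sep = ":")
  dup <- which(duplicated(pd))
  if (length(dup)) {
    nd_validation_error("more than one event_recall-arm record for participant-day '%s'",
                        pd[dup[1]])
  }
  rownames(recalls) <- NULL
  recalls
}

validate_days <- function(days, events) {
  days <- check_columns(as.data.frame(days), DAYS_COLUMNS, "days")
  days$participant_id <- as.character(days$participant_id)
  v <- days$day_index
  bad <- which(!is_whole(v) | v < 1L)
  if (length(bad)) nd_validation_error("days row %d: day_index must be an integer >= 1", bad[1])
  days$day_index <- as.integer(v)
  bad <- which(!is.finite(days$day_positivity))
  if (length(bad)) nd_validation_error("days row %d: day_positivity must be finite", bad[1])
  pd <- paste(days$participant_id, days$day_index, sep = ":")
  dup <- which(duplicated(pd))
  if (length(dup)) nd_validation_error("days: duplicate participant-day '%s'", pd[dup[1]])
  new_days <- unique(paste(events$participant_id[events$regularity == "new"],
                           events$day_index[events$regularity == "new"], sep = ":"))
  days$has_new_event <- pd %in% new_days
  rownames(days) <- NULL
  days
}

#' Read a diary dataset from delimited or JSON-lines files
#'
#' Reads the events, recalls and (optionally) days tables and returns a
#' validated [as_diary_dataset()] object. Row order is preserved. The `csv`
#' dialect expects UTF-8 files with the documented headers; `jsonl` expects
#' one JSON object per line with the same keys.
#'
#' @param events_path path to the events table.
#' @param recalls_path path to the recalls table, or `NULL`.
#' @param days_path path to the days table, or `NULL`.
#' @param dialect `"csv"` or `"jsonl"`.
#' @return A `diary_dataset`.
#' @export
read_dataset <- function(events_path, recalls_path = NULL, days_path = NULL,
                         dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  read_one <- function(path) {
    if (!file.exists(path)) nd_io_error("file not found: %s", path)
    if (dialect == "csv") {
      utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                      fileEncoding = "UTF-8")
    } else {
      con <- file(path, open = "r", encoding = "UTF-8")
      on.exit(close(con))
      jsonlite::stream_in(con, verbose = FALSE)
    }
  }
  events <- read_one(events_path)
  recalls <- if (!is.null(recalls_path)) read_one(recalls_path)
  days <- if (!is.null(days_path)) read_one(days_path)
  as_diary_dataset(events, recalls, days)
}

#' Write a diary dataset back to disk
#'
#' Serializes the component tables so that `read_dataset()` on the written
#' files reproduces the dataset exactly (field-level identity on valid data).
#' The derived `has_new_event` column is not written; it is re-derived on read.
#'
#' @param dataset a `diary_dataset`.
#' @param events_path,recalls_path,days_path output paths (recalls/days written
#'   only when present in the dataset and a path is given).
#' @param dialect `"csv"` or `"jsonl"`.
#' @return `invisible(NULL)`.
#' @export
write_dataset <- function(dataset, events_path, recalls_path = NULL,
                          days_path = NULL, dialect = c("csv", "jsonl")) {
  stopifnot(inherits(dataset, "diary_dataset"))
  dialect <- match.arg(dialect)
  write_one <- function(df, path) {
    if (dialect == "csv") {
      utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                       na = "")
    } else {
      con <- file(path, open = "w", encoding = "UTF-8")
      on.exit(close(con))
      jsonlite::stream_out(df, con, verbose = FALSE)
    }
    invisible(NULL)
  }
  write_one(dataset$events, events_path)
  if (!is.null(dataset$recalls) && !is.null(recalls_path)) {
    write_one(dataset$recalls, recalls_path)
  }
  if (!is.null(dataset$days) && !is.null(days_path)) {
    write_one(dataset$days[, DAYS_COLUMNS, drop = FALSE], days_path)
  }
  invisible(NULL)
}

#' @export
#' @method print diary_dataset
print.diary_dataset <- function(x, ...) {
  cat("Diary dataset\n")
  cat(sprintf("  events:   %d (%d participants)\n", nrow(x$events),
              length(unique(x$events$participant_id))))
  if (!is.null(x$recalls)) {
    cat(sprintf("  recalls:  %d tested (%d with free recall)\n", nrow(x$recalls),
                sum(x$recalls$test_arm == "event_recall")))
  }
  if (!is.null(x$days)) cat(sprintf("  days:     %d participant-days\n", nrow(x$days)))
  tab <- table(factor(x$events$regularity, levels = REGULARITY_LEVELS))
  cat("  regularity: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @method summary diary_dataset
summary.diary_dataset <- function(object, ...) {
  ev <- object$events
  out <- list(
    n_events = nrow(ev),
    n_participants = length(unique(ev$participant_id)),
    events_per_participant = as.vector(table(ev$participant_id)),
    regularity = table(factor(ev$regularity, levels = REGULARITY_LEVELS)),
    n_recalled = if (is.null(object$recalls)) NA_integer_ else
      sum(object$recalls$test_arm == "event_recall")
  )
  class(out) <- "summary.diary_dataset"
  out
}

#' @export
#' @method print summary.diary_dataset
print.summary.diary_dataset <- function(x, ...) {
  cat(sprintf("%d events from %d participants (median %g events each)\n",
              x$n_events, x$n_participants,
              stats::median(x$events_per_participant)))
  print(x$regularity)
  if (!is.na(x$n_recalled)) cat(sprintf("%d events with free recall\n", x$n_recalled))
  invisible(x)
}

#' Write a per-event metrics table
#'
#' One row per event in `metrics`, carrying the derived scores (RSS, RES,
#' stability, detail counts). Values are written with 17 significant digits so
#' that a write/read round trip is lossless to at least 12 digits.
#'
#' @param dataset the `diary_dataset` the metrics were computed from; every
#'   event in `metrics` must exist in it.
#' @param metrics a data.frame as returned by [compute_metrics()] (may have
#'   zero rows, in which case a header-only file is written).
#' @param path output CSV path.
#' @return `invisible(NULL)`.
#' @export
write_metrics_table <- function(dataset, metrics, path) {
  stopifnot(inherits(dataset, "diary_dataset"), is.data.frame(metrics))
  ekey <- event_key(dataset$events$participant_id, dataset$events$day_index,
                    dataset$events$event_index)
  if (nrow(metrics) > 0L) {
    mkey <- event_key(metrics$participant_id, metrics$day_index, metrics$event_index)
    missing <- which(!(mkey %in% ekey))
    if (length(missing)) {
      nd_referential_error("metrics row %d: event '%s' not present in dataset",
                           missing[1], mkey[missing[1]])
    }
  }
  out <- metrics
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), "", format(v, digits = 17, scientific = TRUE, trim = TRUE))
  })
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) nd_io_error("cannot write metrics table to '%s'", path)
  invisible(NULL)
}

#' Read a per-event metrics table written by [write_metrics_table()]
#'
#' @param path CSV path.
#' @return data.frame of per-event metrics.
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) nd_io_error("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  for (col in intersect(c("rss", "res", "stability"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}
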