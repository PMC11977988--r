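#' Read minute-level heart-rate records
#'
#' Reads a CSV of timestamped heart-rate measurements carrying the raw
#' software-version string and hardware product identifier of the recording
#' device. Timestamps are treated as timezone-naive local instants (days are
#' the user's local calendar days) and are stored internally with a fixed UTC
#' label. Exact duplicate rows are dropped; rows with an unparseable
#' timestamp, a missing participant id, or a non-positive `bpm` are rejected
#' and counted in a message.
#'
#' @param path Path to a CSV with header columns `participant_id`,
#'   `timestamp` (ISO-8601 date-time), `bpm`, `source_version`,
#'   `product_type`.
#' @return A tibble sorted by (`participant_id`, `timestamp`) with those five
#'   columns; `timestamp` is `POSIXct`, `bpm` numeric.
#' @export
read_heart_rate_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  require_columns(df, c("participant_id", "timestamp", "bpm", "source_version",
                        "product_type"), path)
  n_raw <- nrow(df)
  df <- dplyr::distinct(df)
  n_dup <- n_raw - nrow(df)

  out <- tibble::tibble(
    participant_id = df$participant_id,
    timestamp = parse_instant(df$timestamp),
    bpm = suppressWarnings(as.numeric(df$bpm)),
    source_version = df$source_version,
    product_type = df$product_type
  )
  bad <- is.na(out$timestamp) | is.na(out$participant_id) |
    is.na(out$bpm) | out$bpm <= 0
  n_bad <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  out <- dplyr::distinct(out) %>% arrange(.data$participant_id, .data$timestamp)
  message(sprintf("read_heart_rate_csv: %d records kept (%d duplicate, %d malformed rows dropped)",
                  nrow(out), n_dup, n_bad))
  out
}

#' Read daily activity summaries
#'
#' One row per participant-day of outcome counts. Duplicate rows with
#' identical values collapse to one; duplicated (`participant_id`, `date`)
#' keys with conflicting values are a hard error. Rows with a negative
#' outcome are rejected and counted.
#'
#' @param path Path to a CSV with header `participant_id`, `date`
#'   (ISO-8601 date), `exercise_minutes`, `active_calories`.
#' @return A tibble with one row per participant-day, sorted.
#' @export
read_daily_activity_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  require_columns(df, c("participant_id", "date", "exercise_minutes",
                        "active_calories"), path)
  out <- tibble::tibble(
    participant_id = df$participant_id,
    date = as.Date(df$date, format = "%Y-%m-%d"),
    exercise_minutes = suppressWarnings(as.numeric(df$exercise_minutes)),
    active_calories = suppressWarnings(as.numeric(df$active_calories))
  )
  out <- dplyr::distinct(out)
  bad <- is.na(out$date) | is.na(out$participant_id) |
    is.na(out$exercise_minutes) | is.na(out$active_calories) |
    out$exercise_minutes < 0 | out$active_calories < 0
  n_bad <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  key_dup <- duplicated(out[, c("participant_id", "date")])
  if (any(key_dup)) {
    ex <- out[key_dup, , drop = FALSE][1, ]
    stop(sprintf("conflicting duplicate daily activity rows for participant %s on %s",
                 ex$participant_id, format(ex$date)))
  }
  out <- arrange(out, .data$participant_id, .data$date)
  message(sprintf("read_daily_activity_csv: %d person-days kept (%d invalid rows dropped)",
                  nrow(out), n_bad))
  out
}

#' Read participant metadata
#'
#' @param path Path to a CSV with header `participant_id`, `sex`
#'   (`male`/`female`).
#' @return A tibble with one row per participant.
#' @export
read_participants_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  require_columns(df, c("participant_id", "sex"), path)
  out <- dplyr::distinct(tibble::tibble(participant_id = df$participant_id,
                                        sex = tolower(df$sex)))
  if (!all(out$sex %in% c("male", "female"))) {
    stop("participants: sex must be 'male' or 'female' for every participant")
  }
  if (anyDuplicated(out$participant_id)) {
    stop("participants: conflicting duplicate participant_id rows")
  }
  out
}

#' Write and re-read a model results table
#'
#' Writes fitted rate ratios as a tidy CSV mirroring the layout of the
#' headline tables: one row per transition label x window type x outcome x
#' stratum x adjustment, with a rendered `rr_cell` string (`"1.00 (0.92,
#' 1.08)"`, 2 decimals) plus full-precision numeric columns so the file
#' round-trips losslessly.
#'
#' @param results Tibble of model results (see [as_model_result()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    stop("write_results_table: results must be non-empty")
  }
  out <- mutate(results, rr_cell = render_rr_cell(.data$rr, .data$ci_low, .data$ci_high))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Render a rate ratio with its 95% CI as a table cell
#'
#' @param rr,ci_low,ci_high Numeric vectors.
#' @return Character vector like `"1.13 (1.06, 1.19)"`; `NA` inputs render
#'   as `"-"` (non-converged cells).
#' @export
render_rr_cell <- function(rr, ci_low, ci_high) {
  if_else(is.na(rr) | is.na(ci_low) | is.na(ci_high), "-",
          sprintf("%.2f (%.2f, %.2f)", rr, ci_low, ci_high))
}

#' Write a simulated cohort to a directory
#'
#' Emits the pipeline's CSV dialects (`heart_rate.csv`, `daily_activity.csv`,
#' `participants.csv`) plus `ground_truth.json`.
#'
#' @param cohort A cohort list from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hr <- mutate(cohort$heart_rate,
               timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  readr::write_csv(hr, file.path(dir, "heart_rate.csv"))
  readr::write_csv(cohort$activity, file.path(dir, "daily_activity.csv"))
  readr::write_csv(cohort$participants, file.path(dir, "participants.csv"))
  gt <- cohort$ground_truth
  gt$events <- as.data.frame(mutate(gt$events,
                                    switch_instant = format(.data$switch_instant,
                                                            "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                                    transition_date = format(.data$transition_date)))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

parse_instant <- function(x) {
  x <- gsub("T", " ", x, fixed = TRUE)
  ts <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  short <- is.na(ts)
  if (any(short)) {
    ts[short] <- as.POSIXct(x[short], tz = "UTC", format = "%Y-%m-%d %H:%M")
  }
  ts
}
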