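#' Participant-level analysis date ranges
#'
#' The range runs from the first to the last calendar date on which a
#' participant has any heart-rate record or (optionally) any activity
#' record; it bounds wear-time estimation.
#'
#' @param records Heart-rate records tibble.
#' @param activity Optional daily activity tibble; extends the range.
#' @return Tibble `participant_id`, `start_date`, `end_date`.
#' @export
participant_date_range <- function(records, activity = NULL) {
  r <- records %>%
    mutate(date = as.Date(.data$timestamp, tz = "UTC")) %>%
    summarise(start_date = min(.data$date), end_date = max(.data$date),
              .by = "participant_id")
  if (!is.null(activity) && nrow(activity)) {
    a <- summarise(activity, a0 = min(.data$date), a1 = max(.data$date),
                   .by = "participant_id")
    r <- dplyr::full_join(r, a, by = "participant_id") %>%
      transmute(.data$participant_id,
                start_date = pmin(.data$start_date, .data$a0, na.rm = TRUE),
                end_date = pmax(.data$end_date, .data$a1, na.rm = TRUE))
  }
  r
}

#' Detect non-wear segments from heart-rate sampling gaps
#'
#' Any interval of `gap_threshold_minutes` or longer (inclusive) without a
#' heart-rate measurement is classified as a non-wear segment: the device is
#' taken to be off-wrist because the optical sensor samples every few minutes
#' while worn. The boundaries of each participant's date range act as virtual
#' measurements at midnight, so a late first measurement on the first day (or
#' a whole date without records inside the range) produces a leading/covering
#' gap.
#'
#' @param records Heart-rate records, sorted by participant and timestamp
#'   (unsorted input is an error).
#' @param gap_threshold_minutes Inclusive gap threshold in minutes
#'   (default 40).
#' @param date_range Optional tibble from [participant_date_range()]; derived
#'   from `records` when omitted.
#' @return Tibble `participant_id`, `start`, `end`, `duration_minutes`, one
#'   row per non-wear segment, non-overlapping within participant.
#' @export
detect_nonwear_segments <- function(records, gap_threshold_minutes = 40,
                                    date_range = NULL) {
  stopifnot(all(c("participant_id", "timestamp") %in% names(records)))
  if (is.null(date_range)) date_range <- participant_date_range(records)

  d <- records %>%
    select("participant_id", "timestamp") %>%
    inner_join(date_range, by = "participant_id")
  unsorted <- d %>%
    mutate(bad = .data$timestamp < lag(.data$timestamp,
                                       default = .data$timestamp[1]),
           .by = "participant_id")
  if (any(unsorted$bad)) {
    stop("detect_nonwear_segments: records must be sorted by timestamp within participant")
  }

  d <- mutate(d,
              prev = lag(.data$timestamp),
              .by = "participant_id")
  first_row <- is.na(d$prev)
  d$prev[first_row] <- midnight_of(d$start_date[first_row])

  inner <- transmute(d, .data$participant_id, start = .data$prev,
                     end = .data$timestamp)
  trailing <- d %>%
    slice_tail_by_participant() %>%
    transmute(.data$participant_id, start = .data$timestamp,
              end = midnight_of(.data$end_date + 1))
  # participants in the range table with no records at all: one covering gap
  empty <- anti_join(date_range, d, by = "participant_id") %>%
    transmute(.data$participant_id, start = midnight_of(.data$start_date),
              end = midnight_of(.data$end_date + 1))

  segs <- bind_rows(inner, trailing, empty) %>%
    mutate(duration_minutes = as.numeric(difftime(.data$end, .data$start,
                                                  units = "mins"))) %>%
    filter(.data$duration_minutes >= gap_threshold_minutes) %>%
    arrange(.data$participant_id, .data$start)
  segs
}

slice_tail_by_participant <- function(d) {
  dplyr::slice_tail(d, n = 1, by = "participant_id")
}

#' Daily wear minutes and valid-day classification
#'
#' Non-wear segments are split at midnight and each part attributed to its
#' own calendar date; a date's non-wear minutes are the sum of its parts,
#' wear is `1440 - nonwear`, and a day is a valid wear day when wear is at
#' least `valid_wear_minutes` ("under 600 minutes" is excluded, so exactly
#' 600 is valid).
#'
#' @param segments Output of [detect_nonwear_segments()].
#' @param date_range Tibble `participant_id`, `start_date`, `end_date`; every
#'   date in range is emitted.
#' @param valid_wear_minutes Minimum wear minutes for a valid day
#'   (default 600).
#' @return Tibble `participant_id`, `date`, `nonwear_minutes`,
#'   `wear_minutes`, `valid_day`; wear + nonwear = 1440 on every row.
#' @export
daily_wear_minutes <- function(segments, date_range, valid_wear_minutes = 600) {
  grid <- date_range %>%
    mutate(ndays = as.integer(.data$end_date - .data$start_date) + 1L) %>%
    tidyr::uncount(.data$ndays, .id = "k") %>%
    transmute(.data$participant_id, date = .data$start_date + .data$k - 1L)

  if (nrow(segments)) {
    parts <- segments %>%
      mutate(d0 = as.Date(.data$start, tz = "UTC"),
             d1 = as.Date(.data$end - 1, tz = "UTC"),
             ndays = as.integer(.data$d1 - .data$d0) + 1L) %>%
      tidyr::uncount(.data$ndays, .id = "k") %>%
      mutate(date = .data$d0 + .data$k - 1L,
             day_start = midnight_of(.data$date),
             day_end = .data$day_start + 86400,
             part = as.numeric(difftime(pmin(.data$end, .data$day_end),
                                        pmax(.data$start, .data$day_start),
                                        units = "mins"))) %>%
      summarise(nonwear_minutes = sum(.data$part),
                .by = c("participant_id", "date"))
  } else {
    parts <- tibble::tibble(participant_id = character(), date = as.Date(character()),
                            nonwear_minutes = numeric())
  }

  grid %>%
    left_join(parts, by = c("participant_id", "date")) %>%
    mutate(nonwear_minutes = pmin(coalesce(.data$nonwear_minutes, 0), 1440),
           wear_minutes = 1440 - .data$nonwear_minutes,
           valid_day = .data$wear_minutes >= valid_wear_minutes)
}

#' Full wear-time estimation for a cohort
#'
#' Convenience wrapper: ranges, segments, then daily wear.
#'
#' @inheritParams detect_nonwear_segments
#' @inheritParams daily_wear_minutes
#' @param activity Optional activity tibble extending the date ranges.
#' @return The [daily_wear_minutes()] tibble.
#' @export
estimate_daily_wear <- function(records, activity = NULL,
                                gap_threshold_minutes = 40,
                                valid_wear_minutes = 600) {
  rng <- participant_date_range(records, activity)
  segs <- detect_nonwear_segments(records, gap_threshold_minutes, rng)
  daily_wear_minutes(segs, rng, valid_wear_minutes)
}
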