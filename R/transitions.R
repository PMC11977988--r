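#' Detect per-participant version transitions
#'
#' A transition date is the first day on which strictly more than half of
#' that day's heart-rate measurements carry the new version ("most" = strict
#' majority; a 50/50 day does not qualify and the scan moves on). Days
#' without a strict-majority version keep the current one. One event is
#' emitted per observed change, so a participant moving 5 -> 6 -> 7 yields
#' two events and a device alternator yields one event per flip.
#'
#' @param day_counts Per-day version counts from [count_day_versions()].
#' @param kind `"software"` or `"hardware"`.
#' @return Tibble `participant_id`, `kind`, `from_version`, `to_version`
#'   (character), `transition_date`.
#' @export
detect_transitions <- function(day_counts, kind = c("software", "hardware")) {
  kind <- match.arg(kind)
  maj <- day_counts %>%
    mutate(total = sum(.data$n), .by = c("participant_id", "date")) %>%
    filter(2 * .data$n > .data$total) %>%
    arrange(.data$participant_id, .data$date)

  ev <- maj %>%
    mutate(prev = lag(.data$version), .by = "participant_id") %>%
    filter(!is.na(.data$prev) & .data$version != .data$prev) %>%
    transmute(.data$participant_id, kind = kind,
              from_version = .data$prev, to_version = .data$version,
              transition_date = .data$date)
  ev
}

.exclusion_reason_levels <- c("non_consecutive", "multiple_software_changes",
                              "hardware_change_in_window",
                              "software_change_in_window",
                              "multiple_hardware_changes", "missing_week")

#' Assess transition eligibility
#'
#' Applies the exclusion rules over the 14-day window (offsets -7..+6 around
#' the transition date, the transition date opening the post week). Software
#' events are ineligible unless consecutive (5->6 ... 8->9), if the major
#' software version changed more than once in the window, if the hardware
#' changed at any point in the window, or if either week has no surviving
#' activity day. Hardware events are ineligible if software changed at any
#' point in the window, if the pre week is not entirely on the old device or
#' the post week not entirely on the new one, or if either week has no
#' surviving activity day. Reasons accumulate; they are not short-circuited.
#'
#' @param events Events from [detect_transitions()].
#' @param day_versions Day-level assignments from [assign_day_versions()].
#' @param activity Activity person-days surviving the filters module
#'   (`participant_id`, `date`); a week of all-invalid days counts as empty.
#' @return `events` plus `label`, `eligible`, `exclusion_reasons`
#'   (list-column of character vectors).
#' @export
assess_eligibility <- function(events, day_versions, activity) {
  if (nrow(events) == 0) {
    return(mutate(events, label = character(0), eligible = logical(0),
                  exclusion_reasons = list()))
  }
  dv_split <- split(day_versions, day_versions$participant_id)
  act_split <- split(activity$date, activity$participant_id)

  res <- purrr::pmap(events, function(participant_id, kind, from_version,
                                      to_version, transition_date, ...) {
    td <- transition_date
    win <- td + (-7:6)
    dv <- dv_split[[participant_id]]
    dv <- dv[dv$date %in% win, , drop = FALSE]
    dv <- dv[order(dv$date), , drop = FALSE]
    act <- act_split[[participant_id]]
    n_pre <- sum(act %in% (td + (-7:-1)))
    n_post <- sum(act %in% (td + (0:6)))

    sw_seq <- dv$major_software[!is.na(dv$major_software)]
    sw_changes <- if (length(sw_seq) > 1) sum(diff(sw_seq) != 0) else 0L
    hw_seq <- dv$hardware_name[!is.na(dv$hardware_name) & dv$hardware_name != "unknown"]
    hw_changes <- if (length(hw_seq) > 1) {
      sum(hw_seq[-1] != hw_seq[-length(hw_seq)])
    } else 0L

    reasons <- character(0)
    if (kind == "software") {
      fv <- suppressWarnings(as.integer(from_version))
      tv <- suppressWarnings(as.integer(to_version))
      if (is.na(fv) || is.na(tv) || tv != fv + 1L || !(fv %in% 5:8)) {
        reasons <- c(reasons, "non_consecutive")
      }
      if (sw_changes > 1) reasons <- c(reasons, "multiple_software_changes")
      if (hw_changes > 0) reasons <- c(reasons, "hardware_change_in_window")
    } else {
      if (sw_changes > 0) reasons <- c(reasons, "software_change_in_window")
      pre_hw <- dv$hardware_name[dv$date < td & !is.na(dv$hardware_name) &
                                   dv$hardware_name != "unknown"]
      post_hw <- dv$hardware_name[dv$date >= td & !is.na(dv$hardware_name) &
                                    dv$hardware_name != "unknown"]
      if (any(pre_hw != from_version) || any(post_hw != to_version)) {
        reasons <- c(reasons, "multiple_hardware_changes")
      }
    }
    if (n_pre == 0 || n_post == 0) reasons <- c(reasons, "missing_week")
    list(eligible = length(reasons) == 0, reasons = reasons)
  })

  events %>%
    mutate(label = transition_label(.data$kind, .data$from_version,
                                    .data$to_version),
           eligible = purrr::map_lgl(res, "eligible"),
           exclusion_reasons = purrr::map(res, "reasons"))
}

transition_label <- function(kind, from_version, to_version) {
  if_else(kind == "hardware", "hardware",
          paste0("watchOS ", from_version, " to ", to_version))
}

#' Build 14-day analysis panels
#'
#' For each eligible event, the treatment panel covers day offsets -7..+6
#' around the transition date (post = 1 from the transition date onward);
#' the control panel covers offsets -14..-1 before the upgrade, with the
#' more recent week (-7..-1) playing the post role — it estimates normal
#' week-to-week variability because no version changes there. A
#' participant-transition enters only if each half-window has at least
#' `completeness_days` surviving activity days (7 = the primary, fully
#' complete analysis; 1, 4, 5, 6 are the sensitivity settings). At most one
#' window per participant per label is kept (the earliest), so a plain
#' random intercept per participant is well-defined downstream.
#'
#' @param events Assessed events (from [assess_eligibility()]); only
#'   eligible ones are used.
#' @param activity Filtered activity person-days with outcomes.
#' @param participants Participant metadata (for `sex`).
#' @param completeness_days Minimum valid activity days per half-window
#'   (default 7).
#' @param window_type `"treatment"` or `"control"`.
#' @return Tibble with columns `label`, `window_type`, `participant_id`,
#'   `date`, `day_offset`, `post`, `weekday`, `transition_weekday`, `sex`,
#'   `exercise_minutes`, `active_calories`.
#' @export
build_panels <- function(events, activity, participants,
                         completeness_days = 7,
                         window_type = c("treatment", "control")) {
  window_type <- match.arg(window_type)
  stopifnot(completeness_days >= 1, completeness_days <= 7)
  offs <- if (window_type == "treatment") -7:6 else -14:-1
  post0 <- if (window_type == "treatment") 0L else -7L

  ev <- events %>%
    filter(.data$eligible) %>%
    arrange(.data$transition_date) %>%
    slice_head(n = 1, by = c("participant_id", "label"))

  empty <- tibble::tibble(label = character(), window_type = character(),
                          participant_id = character(), date = as.Date(character()),
                          day_offset = integer(), post = integer(),
                          weekday = factor(character(), levels = .weekday_levels),
                          transition_weekday = factor(character(), levels = .weekday_levels),
                          sex = character(), exercise_minutes = numeric(),
                          active_calories = numeric())
  if (nrow(ev) == 0) {
    message("build_panels: no eligible events")
    return(empty)
  }

  rows <- ev %>%
    select("participant_id", "label", "transition_date") %>%
    cross_join(tibble::tibble(day_offset = offs)) %>%
    mutate(date = .data$transition_date + .data$day_offset,
           post = as.integer(.data$day_offset >= post0)) %>%
    inner_join(activity, by = c("participant_id", "date")) %>%
    mutate(n_pre = sum(.data$post == 0L), n_post = sum(.data$post == 1L),
           .by = c("participant_id", "label")) %>%
    filter(.data$n_pre >= completeness_days, .data$n_post >= completeness_days)

  if (nrow(rows) == 0) {
    message(sprintf("build_panels(%s): 0 of %d eligible events met completeness %d",
                    window_type, nrow(ev), completeness_days))
    return(empty)
  }
  rows %>%
    left_join(participants, by = "participant_id") %>%
    transmute(.data$label, window_type = window_type, .data$participant_id,
              .data$date, .data$day_offset, .data$post,
              weekday = weekday_of(.data$date),
              transition_weekday = weekday_of(.data$transition_date),
              .data$sex, .data$exercise_minutes, .data$active_calories) %>%
    arrange(.data$label, .data$participant_id, .data$day_offset)
}

#' Tally exclusion reasons across events
#'
#' @param events Assessed events.
#' @return Tibble `reason`, `n` over all occurrences (an event may carry
#'   several reasons).
#' @export
exclusion_ledger <- function(events) {
  reasons <- unlist(events$exclusion_reasons)
  tibble::tibble(reason = factor(reasons, levels = .exclusion_reason_levels)) %>%
    count(.data$reason, .drop = FALSE)
}
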