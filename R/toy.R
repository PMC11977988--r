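#' A deterministic, hand-checkable worked example cohort
#'
#' Seven participants observed 2021-08-23 to 2021-10-10 with heart-rate
#' samples every 6 minutes, built so that every pipeline rule is exercised
#' by a known case:
#'
#' * `T01` (female): clean watchOS 7 to 8 transition. 2021-09-19 has exactly
#'   half of its measurements on the new version (not a strict majority), so
#'   the transition date is 2021-09-20. Planted wear features: a 40.0-minute
#'   gap on 09-14 (inclusive threshold -> one segment), a 39-minute gap on
#'   09-15 (no segment), and two 420-minute gaps on 09-13 giving exactly 600
#'   wear minutes (a valid day). Her device alternates between two product
#'   identifiers of the same generation, which must not register as a
#'   hardware change.
#' * `T02`: software 7 to 8 with a hardware change on day +3 — the software
#'   event is excluded for `hardware_change_in_window`, and the hardware
#'   event for `software_change_in_window`.
#' * `T03`: jumps watchOS 5 to 7 — `non_consecutive`.
#' * `T04`: upgrades 6 to 7 and then 7 to 8 four days later — both events
#'   carry `multiple_software_changes` (each lies inside the other's
#'   window).
#' * `T05`: alternates Series 4 / Series 6 for four days — both hardware
#'   events carry `multiple_hardware_changes`.
#' * `T06`: clean 7 to 8 but no activity in the post week — `missing_week`.
#' * `T07`: clean hardware change (Series 5 to Series 8) — eligible.
#'
#' One sacrificial maximum-outcome day per sex and outcome is planted
#' outside every analysis window, so the 99.9th-percentile filter removes
#' exactly those days and never touches a window.
#'
#' @return List with `participants`, `heart_rate`, `activity`, and
#'   `expected` (frozen expectations: `events` with eligibility and reason
#'   sets, and `wear` rows for the planted days).
#' @export
generate_worked_toy <- function() {
  start <- as.Date("2021-08-23")
  end <- as.Date("2021-10-10")
  days <- seq(start, end, by = "day")
  td <- as.Date("2021-09-20")

  participants <- tibble::tibble(
    participant_id = sprintf("T%02d", 1:7),
    sex = c("female", rep("male", 6))
  )

  grid <- tidyr::expand_grid(date = days, minute = seq(0, 1434, by = 6))

  sw_switch <- function(g, old, new, instant) {
    t <- midnight_of(g$date) + g$minute * 60
    if_else(t < instant, old, new)
  }

  mk <- function(p, g, source_version, product_type) {
    tibble::tibble(participant_id = p,
                   timestamp = midnight_of(g$date) + g$minute * 60,
                   bpm = 75 + (g$minute %% 7),
                   source_version = source_version,
                   product_type = product_type) %>%
      arrange(.data$timestamp)
  }

  ## T01: planted gaps + half-share day
  g1 <- grid %>%
    filter(!(.data$date == as.Date("2021-09-13") &
               !(.data$minute <= 180 |
                   (.data$minute >= 600 & .data$minute <= 660) |
                   .data$minute >= 1080)),
           !(.data$date == as.Date("2021-09-14") &
               .data$minute > 480 & .data$minute < 520),
           !(.data$date == as.Date("2021-09-15") &
               .data$minute > 480 & .data$minute < 519)) %>%
    bind_rows(tibble::tibble(date = as.Date(c("2021-09-14", "2021-09-15")),
                             minute = c(520, 519))) %>%
    arrange(.data$date, .data$minute)
  hr1 <- mk("T01", g1,
            sw_switch(g1, "7.6.1", "8.0.1",
                      midnight_of(as.Date("2021-09-19")) + 720 * 60),
            if_else(as.integer(g1$date - start) %% 2L == 0L,
                    "Watch6,6", "Watch6,7"))

  ## T02: software switch at 09-20 00:00, hardware at 09-23 00:00
  hr2 <- mk("T02", grid,
            sw_switch(grid, "7.6.1", "8.0.1", midnight_of(td)),
            if_else(midnight_of(grid$date) + grid$minute * 60 <
                      midnight_of(as.Date("2021-09-23")),
                    "Watch5,1", "Watch6,1"))

  ## T03: 5 -> 7 jump
  hr3 <- mk("T03", grid, sw_switch(grid, "5.3.8", "7.1", midnight_of(td)),
            "Watch4,1")

  ## T04: 6 -> 7 on 09-16, 7 -> 8 on 09-20
  v4 <- dplyr::case_when(
    grid$date < as.Date("2021-09-16") ~ "6.2.8",
    grid$date < td ~ "7.0",
    TRUE ~ "8.0"
  )
  hr4 <- mk("T04", grid, v4, "Watch4,2")

  ## T05: hardware alternator, Series 4 / Series 6 / Series 4
  p5 <- dplyr::case_when(
    grid$date < td ~ "Watch4,3",
    grid$date < as.Date("2021-09-24") ~ "Watch6,2",
    TRUE ~ "Watch4,3"
  )
  hr5 <- mk("T05", grid, "8.1", p5)

  ## T06: clean 7 -> 8, activity missing in post week
  hr6 <- mk("T06", grid, sw_switch(grid, "7.6.1", "8.0.1", midnight_of(td)),
            "Watch5,2")

  ## T07: clean hardware change Series 5 -> Series 8
  hr7 <- mk("T07", grid, "8.1.1",
            if_else(grid$date < td, "Watch5,3", "Watch6,14"))

  heart_rate <- bind_rows(hr1, hr2, hr3, hr4, hr5, hr6, hr7) %>%
    arrange(.data$participant_id, .data$timestamp)

  ## activity: deterministic mid-range values, plus sacrificial maxima
  activity <- tidyr::expand_grid(participant_id = participants$participant_id,
                                 date = days) %>%
    mutate(k = as.integer(.data$date - start),
           exercise_minutes = 40 + .data$k %% 7,
           active_calories = 600 + 3 * (.data$k %% 5)) %>%
    select(-"k") %>%
    filter(!(.data$participant_id == "T06" &
               .data$date >= td & .data$date <= td + 6))
  put <- function(a, p, d, col, v) {
    i <- a$participant_id == p & a$date == as.Date(d)
    a[[col]][i] <- v
    a
  }
  activity <- activity %>%
    put("T01", "2021-10-05", "exercise_minutes", 150) %>%
    put("T01", "2021-10-06", "active_calories", 1500) %>%
    put("T04", "2021-10-05", "exercise_minutes", 160) %>%
    put("T04", "2021-10-06", "active_calories", 1600)

  expected_events <- tibble::tibble(
    participant_id = c("T01", "T02", "T02", "T03", "T04", "T04", "T05",
                       "T05", "T06", "T07"),
    kind = c("software", "software", "hardware", "software", "software",
             "software", "hardware", "hardware", "software", "hardware"),
    from_version = c("7", "7", "Series 5", "5", "6", "7", "Series 4",
                     "Series 6", "7", "Series 5"),
    to_version = c("8", "8", "Series 6", "7", "7", "8", "Series 6",
                   "Series 4", "8", "Series 8"),
    transition_date = as.Date(c("2021-09-20", "2021-09-20", "2021-09-23",
                                "2021-09-20", "2021-09-16", "2021-09-20",
                                "2021-09-20", "2021-09-24", "2021-09-20",
                                "2021-09-20")),
    eligible = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, TRUE),
    reasons = list(character(0), "hardware_change_in_window",
                   "software_change_in_window", "non_consecutive",
                   "multiple_software_changes", "multiple_software_changes",
                   "multiple_hardware_changes", "multiple_hardware_changes",
                   "missing_week", character(0))
  )
  expected_wear <- tibble::tibble(
    participant_id = "T01",
    date = as.Date(c("2021-09-12", "2021-09-13", "2021-09-14", "2021-09-15")),
    nonwear_minutes = c(0, 840, 40, 0),
    wear_minutes = c(1440, 600, 1400, 1440),
    valid_day = c(TRUE, TRUE, TRUE, TRUE)
  )

  list(participants = participants, heart_rate = heart_rate,
       activity = activity,
       expected = list(events = expected_events, wear = expected_wear,
                       sacrificial_days = tibble::tibble(
                         participant_id = c("T01", "T01", "T04", "T04"),
                         date = as.Date(c("2021-10-05", "2021-10-06",
                                          "2021-10-05", "2021-10-06")))))
}
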