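counts_from_shares <- function(shares, per_day = 10, d0 = as.Date("2021-09-01"),
                               old = "7", new = "8", pid = "A") {
  purrr::map(seq_along(shares), function(i) {
    n_new <- round(shares[i] * per_day)
    tibble::tibble(participant_id = pid, date = d0 + i - 1,
                   version = c(old, new), n = c(per_day - n_new, n_new))
  }) |> dplyr::bind_rows() |> dplyr::filter(n > 0)
}

test_that("transition date is the first strict-majority day of the new version", {
  ev <- detect_transitions(counts_from_shares(c(0.2, 0.4, 0.6, 1.0)), "software")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$transition_date, as.Date("2021-09-03"))
  expect_equal(c(ev$from_version, ev$to_version), c("7", "8"))

  # a 50/50 day is not "most": the scan moves to the next qualifying day
  ev2 <- detect_transitions(counts_from_shares(c(0.0, 0.5, 0.9)), "software")
  expect_equal(ev2$transition_date, as.Date("2021-09-03"))
})

test_that("successive upgrades give one event per change", {
  cc <- dplyr::bind_rows(
    counts_from_shares(rep(0, 2), old = "5", new = "6"),
    counts_from_shares(rep(1, 14), old = "5", new = "6",
                       d0 = as.Date("2021-09-03")),
    counts_from_shares(rep(1, 14), old = "6", new = "7",
                       d0 = as.Date("2021-09-17"))
  )
  ev <- detect_transitions(cc, "software")
  expect_equal(nrow(ev), 2)
  expect_equal(ev$to_version, c("6", "7"))
})

test_that("non-consecutive software jumps are flagged", {
  d0 <- as.Date("2021-09-01")
  cc <- counts_from_shares(c(rep(0, 10), rep(1, 10)), old = "5", new = "7")
  ev <- detect_transitions(cc, "software")
  dv <- tibble::tibble(participant_id = "A", date = d0 + 0:19,
                       major_software = c(rep(5L, 10), rep(7L, 10)),
                       hardware_name = "Series 5")
  act <- tibble::tibble(participant_id = "A", date = d0 + 0:19,
                        exercise_minutes = 40, active_calories = 600)
  out <- assess_eligibility(ev, dv, act)
  expect_false(out$eligible)
  expect_equal(out$exclusion_reasons[[1]], "non_consecutive")
})

test_that("a hardware swap inside a software window is an exclusion reason", {
  d0 <- as.Date("2021-09-01")
  cc <- counts_from_shares(c(rep(0, 10), rep(1, 10)), old = "7", new = "8")
  ev <- detect_transitions(cc, "software")
  td <- ev$transition_date
  dv <- tibble::tibble(participant_id = "A", date = d0 + 0:19,
                       major_software = c(rep(7L, 10), rep(8L, 10)),
                       hardware_name = dplyr::if_else(d0 + 0:19 >= td + 3,
                                                      "Series 7", "Series 5"))
  act <- tibble::tibble(participant_id = "A", date = d0 + 0:19,
                        exercise_minutes = 40, active_calories = 600)
  out <- assess_eligibility(ev, dv, act)
  expect_equal(out$exclusion_reasons[[1]], "hardware_change_in_window")
})

make_panel_inputs <- function(missing_dates = as.Date(character())) {
  d0 <- as.Date("2021-09-01")
  td <- as.Date("2021-09-20")
  ev <- tibble::tibble(participant_id = "A", kind = "software",
                       from_version = "7", to_version = "8",
                       transition_date = td, label = "watchOS 7 to 8",
                       eligible = TRUE, exclusion_reasons = list(character(0)))
  act <- tibble::tibble(participant_id = "A", date = seq(d0, td + 10, by = "day"),
                        exercise_minutes = 40, active_calories = 600)
  act <- act[!act$date %in% missing_dates, ]
  parts <- tibble::tibble(participant_id = "A", sex = "male")
  list(ev = ev, act = act, parts = parts, td = td)
}

test_that("panel completeness rules follow the sensitivity thresholds", {
  x <- make_panel_inputs()
  pan <- build_panels(x$ev, x$act, x$parts, completeness_days = 7)
  expect_equal(nrow(pan), 14)
  expect_equal(sort(pan$day_offset), -7:6)
  expect_equal(pan$post, as.integer(pan$day_offset >= 0))

  # missing day +2: full completeness drops the participant, 6 keeps 13 rows
  x2 <- make_panel_inputs(missing_dates = x$td + 2)
  expect_equal(nrow(quiet(build_panels(x2$ev, x2$act, x2$parts, 7))), 0)
  expect_equal(nrow(build_panels(x2$ev, x2$act, x2$parts, 6)), 13)
})

test_that("control windows precede the upgrade and overlap treatment on -7..-1", {
  x <- make_panel_inputs()
  tr <- build_panels(x$ev, x$act, x$parts, 7, "treatment")
  ct <- build_panels(x$ev, x$act, x$parts, 7, "control")
  expect_true(all(ct$date < x$td))
  expect_equal(sort(ct$day_offset), -14:-1)
  expect_equal(ct$post, as.integer(ct$day_offset >= -7))
  expect_equal(sort(intersect(tr$date, ct$date)),
               sort(as.numeric(x$td + (-7:-1))))
})

test_that("raising completeness never adds participants", {
  set.seed(55)
  x <- make_panel_inputs()
  # second participant with a sparse post week (4 of 7 days)
  act2 <- dplyr::bind_rows(
    x$act,
    tibble::tibble(participant_id = "B",
                   date = c(x$td + (-7:-1), x$td + c(0, 2, 4, 6)),
                   exercise_minutes = 30, active_calories = 500))
  ev2 <- dplyr::bind_rows(x$ev, dplyr::mutate(x$ev, participant_id = "B"))
  parts2 <- tibble::tibble(participant_id = c("A", "B"), sex = "male")
  n_at <- vapply(c(1, 4, 5, 6, 7), function(k) {
    dplyr::n_distinct(quiet(build_panels(ev2, act2, parts2, k))$participant_id)
  }, numeric(1))
  expect_equal(n_at, c(2, 2, 1, 1, 1))
  expect_true(all(diff(n_at) <= 0))
})
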