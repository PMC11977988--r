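make_activity <- function(f_ex, m_ex, f_cal = NULL, m_cal = NULL,
                          d0 = as.Date("2021-01-01")) {
  f_cal <- f_cal %||% (f_ex * 10)
  m_cal <- m_cal %||% (m_ex * 10)
  act <- dplyr::bind_rows(
    tibble::tibble(participant_id = "F1", date = d0 + seq_along(f_ex) - 1,
                   exercise_minutes = f_ex, active_calories = f_cal),
    tibble::tibble(participant_id = "M1", date = d0 + seq_along(m_ex) - 1,
                   exercise_minutes = m_ex, active_calories = m_cal))
  parts <- tibble::tibble(participant_id = c("F1", "M1"),
                          sex = c("female", "male"))
  list(act = act, parts = parts)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("thresholds follow the interpolated 99.9th percentile per sex", {
  x <- make_activity(rep(25, 1000), c(rep(0, 999), 100))
  thr <- quiet(percentile_thresholds(x$act, x$parts))
  # 1000 identical values: the threshold is that value
  expect_equal(thr$threshold[thr$sex == "female" &
                               thr$outcome == "exercise_minutes"], 25)
  # 999 zeros + one 100, type-7 interpolation: h = 999*0.999 + 1 -> 0.1
  expect_equal(thr$threshold[thr$sex == "male" &
                               thr$outcome == "exercise_minutes"], 0.1)
  # strata differ when the distributions differ
  expect_false(thr$threshold[1] == thr$threshold[3])
})

test_that("a sex stratum with no person-days is an error", {
  x <- make_activity(rep(25, 10), rep(30, 10))
  expect_error(
    quiet(percentile_thresholds(x$act[x$act$participant_id == "M1", ], x$parts)),
    "female")
})

test_that("wear-time boundary: 599 minutes excluded, 600 retained", {
  # strictly increasing outcome values so only the top day is a percentile
  # outlier and the early boundary days are judged on wear alone
  x <- make_activity(seq(10, 70, length.out = 1200),
                     seq(15, 80, length.out = 1200))
  wear <- dplyr::mutate(x$act[, c("participant_id", "date")],
                        wear_minutes = 1440, nonwear_minutes = 0,
                        valid_day = TRUE)
  wear$wear_minutes[1] <- 599
  wear$wear_minutes[2] <- 600
  thr <- quiet(percentile_thresholds(x$act, x$parts))
  out <- quiet(apply_exclusions(x$act, wear, thr, x$parts))
  ex1 <- out$exclusions[out$exclusions$participant_id == "F1" &
                          out$exclusions$date == x$act$date[1], ]
  expect_equal(as.character(ex1$reason), "low_wear")
  expect_true(any(out$activity$participant_id == "F1" &
                    out$activity$date == x$act$date[2]))
})

test_that("the maximal-outcome day in a large synthetic set is excluded as an outlier", {
  set.seed(77)
  n <- 5000
  x <- make_activity(stats::rexp(n, 1 / 40), stats::rexp(n, 1 / 50))
  wear <- dplyr::mutate(x$act[, c("participant_id", "date")],
                        wear_minutes = 1440)
  thr <- quiet(percentile_thresholds(x$act, x$parts))
  out <- quiet(apply_exclusions(x$act, wear, thr, x$parts))
  i_max <- which.max(x$act$exercise_minutes)
  expect_true(any(out$exclusions$participant_id == x$act$participant_id[i_max] &
                    out$exclusions$date == x$act$date[i_max] &
                    out$exclusions$reason == "outlier_exercise"))
  # about 0.1% of person-days per sex are removed by each outlier rule
  n_out <- sum(out$exclusions$reason == "outlier_exercise")
  expect_gte(n_out, 2)            # at least the top day per sex
  expect_lte(n_out, 0.004 * 2 * n)
})

test_that("filtering is idempotent at fixed thresholds", {
  set.seed(78)
  n <- 2000
  x <- make_activity(stats::rexp(n, 1 / 40), stats::rexp(n, 1 / 50))
  wear <- dplyr::mutate(x$act[, c("participant_id", "date")],
                        wear_minutes = sample(c(1440, 500), 2 * n, TRUE, c(.9, .1)))
  thr <- quiet(percentile_thresholds(x$act, x$parts))
  once <- quiet(apply_exclusions(x$act, wear, thr, x$parts))
  twice <- quiet(apply_exclusions(once$activity, wear, thr, x$parts))
  expect_equal(twice$activity, once$activity)
  expect_equal(nrow(twice$exclusions), 0)
})
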