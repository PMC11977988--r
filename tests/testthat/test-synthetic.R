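test_that("the generator is deterministic given a seed", {
  a <- quiet(generate_cohort(generator_config(n_participants = 8, seed = 5)))
  b <- quiet(generate_cohort(generator_config(n_participants = 8, seed = 5)))
  expect_identical(a$heart_rate, b$heart_rate)
  expect_identical(a$activity, b$activity)
  expect_identical(a$ground_truth$events, b$ground_truth$events)
  c2 <- quiet(generate_cohort(generator_config(n_participants = 8, seed = 6)))
  expect_false(identical(a$activity, c2$activity))
})

test_that("generator config validates keys and values", {
  expect_error(generator_config(not_a_key = 1), "not_a_key")
  expect_error(generator_config(n_participants = 0), "n_participants")
  expect_error(generator_config(p_missing_day = 1.2), "probabilities")
})

test_that("with no effects and no heterogeneity the empirical means hit the baselines", {
  cfg <- generator_config(
    n_participants = 150, seed = 31,
    end_date = "2020-12-31",
    sigma_b = c(exercise_minutes = 0, active_calories = 0),
    weekday_effect = c(Mon = 1, Tue = 1, Wed = 1, Thu = 1, Fri = 1,
                       Sat = 1, Sun = 1),
    p_missing_day = 0)
  co <- quiet(generate_cohort(cfg))
  expect_gte(nrow(co$activity), 1e5)
  act <- dplyr::inner_join(co$activity, co$participants, by = "participant_id")
  m <- dplyr::summarise(act, ex = mean(exercise_minutes),
                        cal = mean(active_calories), .by = sex)
  for (s in c("female", "male")) {
    expect_lt(abs(m$ex[m$sex == s] /
                    cfg$baseline_mean$exercise_minutes[[s]] - 1), 0.02)
    expect_lt(abs(m$cal[m$sex == s] /
                    cfg$baseline_mean$active_calories[[s]] - 1), 0.02)
  }
})

test_that("simulated outcomes carry NB2 variance mu + alpha mu^2", {
  set.seed(41)
  pan <- simulate_panel(3000, 1.0, sigma_b = 0, baseline_mean = 48.97,
                        alpha = 0.45)
  y <- pan$exercise_minutes
  mu <- 48.97
  expect_lt(abs(mean(y) / mu - 1), 0.02)
  expect_lt(abs(stats::var(y) / (mu + 0.45 * mu^2) - 1), 0.05)
})

test_that("software versions are non-decreasing in time for every participant", {
  co <- quiet(generate_cohort(generator_config(n_participants = 20, seed = 13)))
  ev <- co$ground_truth$events
  sw <- ev[ev$kind == "software", ]
  ok <- vapply(split(sw, sw$participant_id), function(e) {
    e <- e[order(e$switch_instant), ]
    all(diff(as.integer(e$to_version)) > 0) &&
      all(as.integer(e$to_version) > as.integer(e$from_version))
  }, logical(1))
  expect_true(all(ok))
  # and in the day-level assignment derived from the records
  dv <- quiet(assign_day_versions(co$heart_rate))
  mono <- dplyr::summarise(
    dplyr::arrange(dv[!is.na(dv$major_software), ], participant_id, date),
    ok = all(diff(major_software) >= 0),
    .by = participant_id)
  expect_true(all(mono$ok))
})

test_that("mean heart-rate sampling interval is close to its configured value", {
  co <- quiet(generate_cohort(generator_config(n_participants = 6, seed = 17)))
  hr <- co$heart_rate[co$heart_rate$participant_id == co$participants$participant_id[1], ]
  gaps <- diff(as.numeric(hr$timestamp)) / 60
  gaps <- gaps[gaps < 40]   # within-wear gaps
  expect_gt(mean(gaps), 4.4)
  expect_lt(mean(gaps), 6.4)
  expect_gte(min(gaps), 1)
})

test_that("the worked toy fixture matches its shipped expectations", {
  toy <- toy_cached()
  w <- quiet(estimate_daily_wear(toy$heart_rate, toy$activity))
  shipped <- readr::read_csv(system.file("extdata", "toy_expected_wear.csv",
                                         package = "wearversion"),
                             show_col_types = FALSE)
  got <- dplyr::inner_join(w, shipped[, c("participant_id", "date")],
                           by = c("participant_id", "date"))
  expect_equal(got$nonwear_minutes, shipped$nonwear_minutes)
  expect_equal(got$wear_minutes, shipped$wear_minutes)
  expect_equal(got$valid_day, shipped$valid_day)
})
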