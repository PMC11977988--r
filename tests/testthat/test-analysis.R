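test_that("person-level change summaries match hand arithmetic", {
  pan <- tibble::tibble(
    label = "watchOS 7 to 8", window_type = "treatment",
    participant_id = rep(c("A", "B"), each = 4),
    date = as.Date("2021-09-18") + rep(0:3, 2),
    day_offset = rep(c(-2, -1, 0, 1), 2),
    post = rep(c(0L, 0L, 1L, 1L), 2),
    weekday = wd_of(as.Date("2021-09-18") + rep(0:3, 2)),
    transition_weekday = wd_of(as.Date("2021-09-20")),
    sex = rep(c("female", "male"), each = 4),
    exercise_minutes = c(40, 40, 44, 44,   30, 30, 37, 37),  # deltas +4, +7
    active_calories = 600)

  cs <- person_level_change(pan, "exercise_minutes")
  expect_equal(cs$mean_change, 5.5)
  expect_equal(cs$sd_change, sqrt(((4 - 5.5)^2 + (7 - 5.5)^2) / 1))
  expect_equal(cs$n, 2L)

  one <- person_level_change(pan[pan$participant_id == "A", ], "exercise_minutes")
  expect_equal(one$mean_change, 4)
  expect_true(is.na(one$sd_change))
  expect_equal(one$n, 1L)

  flat <- person_level_change(dplyr::mutate(pan, active_calories = 600),
                              "active_calories")
  expect_equal(flat$mean_change, 0)
  expect_equal(flat$sd_change, 0)

  f <- person_level_change(pan, "exercise_minutes", "female")
  expect_equal(f$mean_change, 4)
  empty <- quiet(person_level_change(pan[pan$sex == "male", ],
                                     "exercise_minutes", "female"))
  expect_equal(empty$n, 0L)
})

test_that("the mixed model collapses to a plain NB regression when sigma_b is 0", {
  skip_if_not_installed("MASS")
  set.seed(9100)
  pan <- simulate_panel(100, 1.0, sigma_b = 0)
  y <- round(pan$exercise_minutes)
  X <- stats::model.matrix(~ post, data = pan)
  ref <- MASS::glm.nb(y ~ post, data = pan)
  # with the random-intercept SD pinned at zero the marginal likelihood is
  # the plain NB likelihood
  pinned <- nbglmm_ml(y, X, pan$participant_id, sigma_fixed = 0)
  expect_lt(max(abs(pinned$beta - stats::coef(ref))), 1e-3)
  expect_lt(abs(pinned$alpha - 1 / ref$theta), 1e-3)
  # and the free fit estimates only sampling-level heterogeneity
  free <- fit_nb_glmm(pan)
  expect_lt(max(abs(free$beta - stats::coef(ref))), 5e-3)
  expect_lt(free$sigma_b, 0.15)
})

test_that("the fit matches an independent mixed-model implementation", {
  skip_if_not_installed("glmmTMB")
  set.seed(9200)
  pan <- simulate_panel(100, 1.10)
  fit <- fit_nb_glmm(pan)
  d <- dplyr::mutate(pan, y = round(exercise_minutes))
  ref <- glmmTMB::glmmTMB(y ~ post + (1 | participant_id),
                          family = glmmTMB::nbinom2, data = d)
  expect_lt(max(abs(fit$beta - glmmTMB::fixef(ref)$cond)), 5e-3)
  expect_lt(abs(fit$sigma_b -
                  sqrt(glmmTMB::VarCorr(ref)$cond$participant_id[1])), 5e-3)
  # adaptive quadrature must not do worse than the Laplace approximation
  expect_gte(fit$loglik, as.numeric(stats::logLik(ref)) - 1e-3)
})

test_that("scaling the post-period outcomes shifts the post coefficient by log(c)", {
  set.seed(9300)
  pan <- simulate_panel(150, 1.0, outcome = "active_calories")
  f0 <- fit_nb_glmm(pan, outcome = "active_calories")
  scl <- exp(0.22314)   # log(1.25)
  pan2 <- dplyr::mutate(pan, active_calories = ifelse(post == 1,
                                                      round(active_calories * scl),
                                                      active_calories))
  f1 <- fit_nb_glmm(pan2, outcome = "active_calories")
  expect_lt(abs((f1$beta[["post"]] - f0$beta[["post"]]) - 0.22314), 0.02)
})

test_that("rate ratio is stable as quadrature nodes increase from 9 to 15", {
  set.seed(9400)
  pan <- simulate_panel(80, 1.13)
  f9 <- fit_nb_glmm(pan, nodes = 9)
  f15 <- fit_nb_glmm(pan, nodes = 15)
  expect_lt(abs(f9$rate_ratio - f15$rate_ratio), 1e-3)
  expect_true(f9$converged)
  expect_true(f9$ci_low <= f9$rate_ratio && f9$rate_ratio <= f9$ci_high)
})

test_that("weekday adjustment leaves the RR almost unchanged without weekday effects", {
  set.seed(9500)
  pan <- simulate_panel(120, 1.05)
  fu <- fit_nb_glmm(pan)
  fa <- fit_nb_glmm(pan, adjust_weekday = TRUE)
  expect_lt(abs(log(fa$rate_ratio) - log(fu$rate_ratio)), 0.02)
  expect_equal(length(fa$beta), 8)  # intercept + post + 6 weekday contrasts
})

test_that("degenerate panels are rejected", {
  pan <- simulate_panel(5, 1.0)
  pan$exercise_minutes <- 0
  expect_error(fit_nb_glmm(pan), "all zero")
  expect_error(fit_nb_glmm(pan, stratum = "female",
                           outcome = "active_calories"),
               "empty|all zero|missing")
})
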