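#' Default marginal parameters for one outcome
#'
#' Baseline daily means are the cohort-level baselines (overall, and by
#' sex); the NB2 dispersion `alpha` and random-intercept SD `sigma_b` (log
#' scale) are calibrated so that simulated panels reproduce both the
#' observed spread of participant pre-week means and the precision of the
#' fitted rate ratios at the study's panel sizes (derivation in the methods
#' vignette).
#'
#' @param outcome `"exercise_minutes"` or `"active_calories"`.
#' @return List with `baseline_mean` (overall), `baseline_by_sex`,
#'   `sigma_b`, `alpha`.
#' @export
panel_defaults <- function(outcome = c("exercise_minutes", "active_calories")) {
  outcome <- match.arg(outcome)
  if (outcome == "exercise_minutes") {
    list(baseline_mean = 48.97,
         baseline_by_sex = c(female = 48.15, male = 49.34),
         sigma_b = 0.57, alpha = 0.45)
  } else {
    list(baseline_mean = 710.43,
         baseline_by_sex = c(female = 594.31, male = 764.17),
         sigma_b = 0.33, alpha = 0.08)
  }
}

#' Simulate an analysis panel directly from the NB2 mixed model
#'
#' Generates the person-day table the transition models consume, with a
#' known multiplicative effect switching exactly at day offset
#' `effect_start` (the transition date). The treatment window covers
#' offsets -7..+6 with post = 1 from offset 0; the control window covers
#' -14..-1 with the -7..-1 week as the post half — since the injected
#' effect only starts at offset 0, control panels are null by construction.
#'
#' @param n_participants Number of participants.
#' @param true_rr True multiplicative post-transition effect.
#' @param outcome Outcome name (sets default baseline, `sigma_b`, `alpha`).
#' @param baseline_mean Marginal mean of the daily outcome (defaults per
#'   outcome).
#' @param sigma_b Random-intercept SD on the log scale.
#' @param alpha NB2 dispersion (variance `mu + alpha mu^2`).
#' @param window_type `"treatment"` or `"control"`.
#' @param effect_start Day offset at which the effect switches on.
#' @param base_date First possible transition date; individual transition
#'   dates spread over four weeks from it so weekdays vary.
#' @param prop_male Probability a participant is male.
#' @param weekday_effect Optional named multiplicative weekday effects
#'   (`Mon`..`Sun`); `NULL` = none.
#' @param label Panel label.
#' @return A panel tibble as from [build_panels()].
#' @export
simulate_panel <- function(n_participants, true_rr = 1,
                           outcome = c("exercise_minutes", "active_calories"),
                           baseline_mean = NULL, sigma_b = NULL, alpha = NULL,
                           window_type = c("treatment", "control"),
                           effect_start = 0L,
                           base_date = as.Date("2021-09-20"),
                           prop_male = 0.61, weekday_effect = NULL,
                           label = "synthetic") {
  outcome <- match.arg(outcome)
  window_type <- match.arg(window_type)
  def <- panel_defaults(outcome)
  baseline_mean <- baseline_mean %||% def$baseline_mean
  sigma_b <- sigma_b %||% def$sigma_b
  alpha <- alpha %||% def$alpha
  offs <- if (window_type == "treatment") -7:6 else -14:-1
  post0 <- if (window_type == "treatment") 0L else -7L

  pid <- sprintf("S%04d", seq_len(n_participants))
  sex <- if_else(runif(n_participants) < prop_male, "male", "female")
  b <- rnorm(n_participants, 0, sigma_b)
  td <- base_date + sample(0:27, n_participants, replace = TRUE)

  d <- tibble::tibble(participant_id = rep(pid, each = length(offs)),
                      sex = rep(sex, each = length(offs)),
                      b = rep(b, each = length(offs)),
                      transition_date = rep(td, each = length(offs)),
                      day_offset = rep(offs, n_participants)) %>%
    mutate(date = .data$transition_date + .data$day_offset,
           post = as.integer(.data$day_offset >= post0),
           weekday = weekday_of(.data$date),
           transition_weekday = weekday_of(.data$transition_date))
  log_mu <- log(baseline_mean) - sigma_b^2 / 2 + d$b +
    log(true_rr) * (d$day_offset >= effect_start)
  if (!is.null(weekday_effect)) {
    log_mu <- log_mu + log(weekday_effect[as.character(d$weekday)])
  }
  y <- rnbinom(nrow(d), mu = exp(log_mu), size = 1 / alpha)

  out <- tibble::tibble(label = label, window_type = window_type,
                        participant_id = d$participant_id, date = d$date,
                        day_offset = d$day_offset, post = d$post,
                        weekday = d$weekday,
                        transition_weekday = d$transition_weekday,
                        sex = d$sex,
                        exercise_minutes = NA_real_, active_calories = NA_real_)
  out[[outcome]] <- as.numeric(y)
  out
}

#' Generator configuration for a synthetic cohort
#'
#' All probabilities, rates, dates and effects driving [generate_cohort()].
#' Defaults describe a cohort of wearable users observed from 2019 onward:
#' sex-specific baseline outcomes, annual software releases adopted within
#' 25-31 days, heart-rate sampling every 5.62 minutes on average (truncated
#' at 1 minute), occasional non-wear blocks, missing activity days, and a
#' small fraction of participants who alternate between two devices.
#' Unknown argument names are an error.
#'
#' @param ... Named overrides of any default field.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_participants = 250,
    proportion_male = 0.61,
    start_date = "2019-01-01",
    end_date = "2022-12-31",
    baseline_mean = list(
      exercise_minutes = c(female = 48.15, male = 49.34),
      active_calories = c(female = 594.31, male = 764.17)
    ),
    sigma_b = c(exercise_minutes = 0.57, active_calories = 0.33),
    alpha = c(exercise_minutes = 0.45, active_calories = 0.08),
    weekday_effect = c(Mon = 1, Tue = 1, Wed = 1, Thu = 1, Fri = 1,
                       Sat = 1.08, Sun = 1.05),
    software_effects = list(
      exercise_minutes = c(`6` = 1, `7` = 1, `8` = 1, `9` = 1),
      active_calories = c(`6` = 1, `7` = 1, `8` = 1, `9` = 1)
    ),
    hardware_effect = c(exercise_minutes = 1, active_calories = 1),
    software_releases = c(`6` = "2019-09-19", `7` = "2020-09-16",
                          `8` = "2021-09-20", `9` = "2022-09-12"),
    hardware_releases = c("Series 5" = "2019-09-20", "Series 6" = "2020-09-18",
                          "Series 7" = "2021-10-15", "Series 8" = "2022-09-16"),
    adoption_lag_days = c(25, 31),
    p_upgrade = 0.95,
    p_hardware_upgrade = 0.40,
    p_alternator = 0.066,
    hr_mean_interval_minutes = 5.62,
    hr_min_interval_minutes = 1,
    nonwear_daily_prob = 0.5,
    nonwear_minutes_range = c(45, 150),
    p_missing_day = 0.06,
    hr_coverage = "windows",
    window_buffer_days = c(-17, 8),
    seed = 1
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      stop(sprintf("generator_config: unknown config key(s): %s",
                   paste(bad, collapse = ", ")))
    }
    cfg[names(over)] <- over
  }
  if (cfg$n_participants < 1) stop("generator_config: n_participants must be >= 1")
  probs <- c(cfg$proportion_male, cfg$p_upgrade, cfg$p_hardware_upgrade,
             cfg$p_alternator, cfg$nonwear_daily_prob, cfg$p_missing_day)
  if (any(probs < 0 | probs > 1)) stop("generator_config: probabilities must lie in [0, 1]")
  if (any(unlist(cfg$software_effects) <= 0) || any(cfg$hardware_effect <= 0)) {
    stop("generator_config: effects must be > 0")
  }
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic HealthKit-like cohort with known ground truth
#'
#' Draws per-participant upgrade schedules (release date + adoption lag,
#' with the version switch at a uniform instant within the adoption day so
#' transition-date detection is genuinely exercised), emits minute-level
#' heart-rate records stamped with the operative software version string and
#' hardware product identifier, and simulates daily NB2 outcomes whose
#' multiplicative upgrade effects switch exactly at the ground-truth
#' transition date. With `hr_coverage = "windows"` (the default) heart-rate
#' streams are emitted only in a buffer neighbourhood of each upgrade — the
#' only days any pipeline stage consumes — keeping the default cohort
#' desk-sized; `"full"` emits every day.
#'
#' @param config A [generator_config()].
#' @return List with `participants`, `heart_rate`, `activity`, and
#'   `ground_truth` (list with `events`: one row per true upgrade, carrying
#'   `switch_instant`, the implied `transition_date`, and the true effects
#'   per outcome).
#' @export
generate_cohort <- function(config = generator_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_participants
  pid <- sprintf("P%04d", seq_len(n))
  sex <- if_else(runif(n) < cfg$proportion_male, "male", "female")
  participants <- tibble::tibble(participant_id = pid, sex = sex)
  start_date <- as.Date(cfg$start_date)
  end_date <- as.Date(cfg$end_date)
  lag_lo <- cfg$adoption_lag_days[1]
  lag_hi <- cfg$adoption_lag_days[2]
  index <- load_hardware_index()

  ## ---- software upgrade schedule ------------------------------------
  sw_rel <- as.Date(cfg$software_releases)
  names(sw_rel) <- names(cfg$software_releases)
  # everyone starts on the newest major version released before the study
  base_version <- max(c(5L, as.integer(names(sw_rel))[sw_rel < start_date]))
  sw <- tidyr::expand_grid(participant_id = pid,
                           to_version = names(sw_rel)) %>%
    mutate(release = sw_rel[.data$to_version]) %>%
    filter(.data$release >= start_date, .data$release <= end_date - lag_hi - 9) %>%
    filter(runif(n()) < cfg$p_upgrade) %>%
    mutate(lag = sample(seq(lag_lo, lag_hi), n(), replace = TRUE),
           frac = runif(n()),
           switch_instant = midnight_of(.data$release + .data$lag) +
             round(.data$frac * 86399)) %>%
    arrange(.data$participant_id, .data$switch_instant) %>%
    mutate(from_version = lag(.data$to_version,
                              default = as.character(base_version)),
           .by = "participant_id") %>%
    mutate(transition_date = .data$release + .data$lag +
             as.integer(.data$frac >= 0.5),
           kind = "software")

  sw_eff <- function(outcome) {
    eff <- cfg$software_effects[[outcome]]
    purrr::map2_dbl(as.integer(sw$from_version), as.integer(sw$to_version),
                    function(f, t) prod(eff[as.character(seq(f + 1, t))]))
  }
  if (nrow(sw)) {
    sw$effect_exercise <- sw_eff("exercise_minutes")
    sw$effect_calories <- sw_eff("active_calories")
  }

  ## ---- hardware schedule --------------------------------------------
  hw_rel <- as.Date(cfg$hardware_releases)
  names(hw_rel) <- names(cfg$hardware_releases)
  initial_hw <- sample(c("Series 3", "Series 4", "Series 5"), n,
                       replace = TRUE, prob = c(0.3, 0.4, 0.3))
  alternator <- runif(n) < cfg$p_alternator
  upgrader <- !alternator & runif(n) < cfg$p_hardware_upgrade
  hw <- tibble::tibble(participant_id = pid, from_version = initial_hw)[upgrader, ]
  usable <- hw_rel[hw_rel >= start_date & hw_rel <= end_date - lag_hi - 9]
  if (nrow(hw) && length(usable)) {
    hw <- hw %>%
      mutate(to_version = sample(names(usable), n(), replace = TRUE)) %>%
      filter(.data$to_version != .data$from_version) %>%
      mutate(release = usable[.data$to_version],
             lag = sample(seq(lag_lo, lag_hi), n(), replace = TRUE),
             frac = runif(n()),
             switch_instant = midnight_of(.data$release + .data$lag) +
               round(.data$frac * 86399),
             transition_date = .data$release + .data$lag +
               as.integer(.data$frac >= 0.5),
             kind = "hardware",
             effect_exercise = unname(cfg$hardware_effect["exercise_minutes"]),
             effect_calories = unname(cfg$hardware_effect["active_calories"]))
  } else {
    hw <- hw[0, ]
  }
  alt_second <- setNames(rep(NA_character_, n), pid)
  if (any(alternator)) {
    alt_second[alternator] <- purrr::map_chr(initial_hw[alternator], function(h) {
      sample(setdiff(c("Series 3", "Series 4", "Series 5", "Series 6"), h), 1)
    })
  }
  alt_period <- setNames(sample(2:5, n, replace = TRUE), pid)

  events <- bind_rows(
    select(sw, "participant_id", "kind", "from_version", "to_version",
           "switch_instant", "transition_date", "effect_exercise",
           "effect_calories"),
    if (nrow(hw)) select(hw, "participant_id", "kind", "from_version",
                         "to_version", "switch_instant", "transition_date",
                         "effect_exercise", "effect_calories")
  ) %>% arrange(.data$participant_id, .data$switch_instant)

  ## ---- heart-rate emission days -------------------------------------
  if (identical(cfg$hr_coverage, "full")) {
    emit <- tidyr::expand_grid(participant_id = pid,
                               date = seq(start_date, end_date, by = "day"))
  } else {
    buf <- cfg$window_buffer_days
    anchor <- events %>% select("participant_id", "transition_date")
    lonely <- setdiff(pid, anchor$participant_id)
    if (length(lonely)) {
      anchor <- bind_rows(anchor, tibble::tibble(
        participant_id = lonely,
        transition_date = start_date + sample.int(90, length(lonely), replace = TRUE)))
    }
    emit <- anchor %>%
      cross_join(tibble::tibble(off = seq(buf[1], buf[2]))) %>%
      transmute(.data$participant_id, date = .data$transition_date + .data$off) %>%
      filter(.data$date >= start_date, .data$date <= end_date) %>%
      distinct() %>%
      arrange(.data$participant_id, .data$date)
  }

  ## pick a concrete product identifier per participant-device
  ids_by_name <- split(index$product_type, index$commercial_name)
  pick_id <- function(p, name) {
    pool <- ids_by_name[[name]]
    pool[1 + (utf8ToInt(substr(p, nchar(p), nchar(p))) %% length(pool))]
  }

  ## ---- generate heart-rate records per contiguous block --------------
  emit <- mutate(emit,
                 block = cumsum(c(1L, as.integer(diff(.data$date) != 1L))),
                 .by = "participant_id")
  blocks <- summarise(emit, d0 = min(.data$date), d1 = max(.data$date),
                      .by = c("participant_id", "block"))
  sw_split <- split(sw, sw$participant_id)
  hw_split <- split(hw, hw$participant_id)
  mean_gap <- cfg$hr_mean_interval_minutes
  min_gap <- cfg$hr_min_interval_minutes

  gen_block <- function(p, d0, d1) {
    ndays <- as.integer(d1 - d0) + 1L
    span <- ndays * 1440
    m <- ceiling(span / mean_gap * 1.15) + 50
    t <- cumsum(min_gap + rexp(m, 1 / (mean_gap - min_gap)))
    while (t[length(t)] < span) {
      t <- c(t, t[length(t)] +
               cumsum(min_gap + rexp(200, 1 / (mean_gap - min_gap))))
    }
    t <- t[t < span]
    day_idx <- floor(t / 1440) + 1L
    min_day <- t - (day_idx - 1L) * 1440
    # daily non-wear blocks
    nw <- runif(ndays) < cfg$nonwear_daily_prob
    dur <- runif(ndays, cfg$nonwear_minutes_range[1], cfg$nonwear_minutes_range[2])
    st <- runif(ndays, 0, 1440 - dur)
    drop <- nw[day_idx] & min_day >= st[day_idx] & min_day < (st + dur)[day_idx]
    t <- t[!drop]
    day_idx <- day_idx[!drop]
    instant <- midnight_of(d0) + round(t * 60)
    tn <- as.numeric(instant)

    # software version at each instant
    s <- sw_split[[p]]
    if (!is.null(s) && nrow(s)) {
      vseq <- c(s$from_version[1], s$to_version)
      major <- vseq[findInterval(tn, as.numeric(s$switch_instant)) + 1L]
    } else {
      major <- rep(as.character(base_version), length(tn))
    }
    minor <- sample(0:3, length(tn), replace = TRUE)
    source_version <- paste0(major, ".", minor, ".1")

    # hardware device at each instant/date
    if (alternator[match(p, pid)]) {
      dts <- as.integer(d0 - start_date) + day_idx - 1L
      name <- if_else((dts %/% alt_period[[p]]) %% 2L == 0L,
                      initial_hw[match(p, pid)], alt_second[[p]])
    } else {
      h <- hw_split[[p]]
      if (!is.null(h) && nrow(h)) {
        name <- if_else(tn < as.numeric(h$switch_instant[1]),
                        h$from_version[1], h$to_version[1])
      } else {
        name <- rep(initial_hw[match(p, pid)], length(tn))
      }
    }
    uniq <- unique(name)
    idmap <- setNames(vapply(uniq, function(u) pick_id(p, u), character(1)), uniq)
    tibble::tibble(participant_id = p, timestamp = instant,
                   bpm = pmin(200, pmax(35, round(rnorm(length(tn), 80, 12)))),
                   source_version = source_version,
                   product_type = unname(idmap[name]))
  }

  heart_rate <- purrr::pmap(
    list(blocks$participant_id, blocks$d0, blocks$d1), gen_block) %>%
    bind_rows() %>%
    arrange(.data$participant_id, .data$timestamp)

  ## ---- daily activity -------------------------------------------------
  all_days <- tidyr::expand_grid(participant_id = pid,
                                 date = seq(start_date, end_date, by = "day"))
  b_ex <- setNames(rnorm(n, 0, cfg$sigma_b[["exercise_minutes"]]), pid)
  b_cal <- setNames(rnorm(n, 0, cfg$sigma_b[["active_calories"]]), pid)
  base_ex <- cfg$baseline_mean$exercise_minutes[sex]
  base_cal <- cfg$baseline_mean$active_calories[sex]
  names(base_ex) <- names(base_cal) <- pid

  eff <- events %>%
    transmute(.data$participant_id, td = .data$transition_date,
              le = log(.data$effect_exercise), lc = log(.data$effect_calories))
  step <- all_days %>%
    inner_join(eff, by = "participant_id", relationship = "many-to-many") %>%
    filter(.data$date >= .data$td) %>%
    summarise(le = sum(.data$le), lc = sum(.data$lc),
              .by = c("participant_id", "date"))

  act <- all_days %>%
    left_join(step, by = c("participant_id", "date")) %>%
    mutate(le = coalesce(.data$le, 0), lc = coalesce(.data$lc, 0),
           wk = log(cfg$weekday_effect[as.character(weekday_of(.data$date))]))
  mu_ex <- exp(log(base_ex[act$participant_id]) -
                 cfg$sigma_b[["exercise_minutes"]]^2 / 2 +
                 b_ex[act$participant_id] + act$wk + act$le)
  mu_cal <- exp(log(base_cal[act$participant_id]) -
                  cfg$sigma_b[["active_calories"]]^2 / 2 +
                  b_cal[act$participant_id] + act$wk + act$lc)
  activity <- tibble::tibble(
    participant_id = act$participant_id, date = act$date,
    exercise_minutes = as.numeric(rnbinom(nrow(act), mu = mu_ex,
                                          size = 1 / cfg$alpha[["exercise_minutes"]])),
    active_calories = as.numeric(rnbinom(nrow(act), mu = mu_cal,
                                         size = 1 / cfg$alpha[["active_calories"]]))
  )
  activity <- activity[runif(nrow(activity)) >= cfg$p_missing_day, , drop = FALSE]

  list(participants = participants, heart_rate = heart_rate,
       activity = activity,
       ground_truth = list(events = events,
                           alternators = pid[alternator],
                           seed = cfg$seed))
}
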