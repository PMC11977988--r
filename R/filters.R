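#' Sex-specific 99.9th-percentile outcome thresholds
#'
#' For each sex and each outcome, the threshold is the 99.9th percentile of
#' all of that sex's person-days, using the linear-interpolation quantile
#' definition (`stats::quantile`, type 7). Thresholds are computed once over
#' the full pre-filter person-day history: pooling within sex is what gives
#' a 0.1% tail useful resolution.
#'
#' @param activity Daily activity tibble.
#' @param participants Participant metadata with `sex`.
#' @param prob Quantile probability (default 0.999).
#' @return Tibble `sex`, `outcome`, `threshold`. A sex stratum with zero
#'   person-days is an error; fewer than 1000 triggers a warning that the
#'   threshold is degenerate.
#' @export
percentile_thresholds <- function(activity, participants, prob = 0.999) {
  missing_sex <- setdiff(unique(activity$participant_id),
                         participants$participant_id)
  if (length(missing_sex)) {
    stop(sprintf("percentile_thresholds: %d participants lack sex metadata (e.g. %s)",
                 length(missing_sex), missing_sex[1]))
  }
  a <- inner_join(activity, participants, by = "participant_id")
  out <- list()
  for (s in c("female", "male")) {
    rows <- a[a$sex == s, , drop = FALSE]
    if (nrow(rows) == 0) {
      stop(sprintf("percentile_thresholds: no person-days for sex '%s'", s))
    }
    if (nrow(rows) < 1000) {
      warning(sprintf("percentile_thresholds: only %d person-days for sex '%s'; thresholds are degenerate",
                      nrow(rows), s))
    }
    out[[s]] <- tibble::tibble(
      sex = s,
      outcome = c("exercise_minutes", "active_calories"),
      threshold = c(unname(quantile(rows$exercise_minutes, prob, type = 7)),
                    unname(quantile(rows$active_calories, prob, type = 7)))
    )
  }
  thr <- bind_rows(out)
  message(paste0("percentile_thresholds: ",
                 paste(sprintf("%s %s = %.2f", thr$sex, thr$outcome, thr$threshold),
                       collapse = "; ")))
  thr
}

#' Apply person-day exclusions
#'
#' Drops person-days whose exercise minutes or active calories reach the
#' sex-specific 99.9th-percentile threshold (the "top 0.1%" reading: at or
#' above the threshold), whose estimated wear is under `min_wear_minutes`,
#' or that have no wear record at all. A day may carry several reasons; the
#' ledger counts each.
#'
#' @param activity Daily activity tibble.
#' @param wear Daily wear tibble from [daily_wear_minutes()].
#' @param thresholds Output of [percentile_thresholds()].
#' @param participants Participant metadata with `sex`.
#' @param min_wear_minutes Minimum wear minutes (default 600; exactly 600 is
#'   retained).
#' @return List with `activity` (surviving rows, original columns),
#'   `exclusions` (tibble `participant_id`, `date`, `reason`), and `ledger`
#'   (counts per reason).
#' @export
apply_exclusions <- function(activity, wear, thresholds, participants,
                             min_wear_minutes = 600) {
  thr_wide <- tidyr::pivot_wider(thresholds, names_from = "outcome",
                                 values_from = "threshold",
                                 names_prefix = "thr_")
  a <- activity %>%
    inner_join(participants, by = "participant_id") %>%
    left_join(thr_wide, by = "sex") %>%
    left_join(select(wear, "participant_id", "date", "wear_minutes"),
              by = c("participant_id", "date")) %>%
    mutate(outlier_exercise = .data$exercise_minutes >= .data$thr_exercise_minutes,
           outlier_calories = .data$active_calories >= .data$thr_active_calories,
           no_wear_record = is.na(.data$wear_minutes),
           low_wear = !is.na(.data$wear_minutes) &
             .data$wear_minutes < min_wear_minutes)

  reasons <- c("outlier_exercise", "outlier_calories", "low_wear",
               "no_wear_record")
  exclusions <- a %>%
    select("participant_id", "date", dplyr::all_of(reasons)) %>%
    tidyr::pivot_longer(dplyr::all_of(reasons), names_to = "reason",
                        values_to = "flag") %>%
    filter(.data$flag) %>%
    select(-"flag") %>%
    mutate(reason = factor(.data$reason, levels = reasons))
  ledger <- count(exclusions, .data$reason, .drop = FALSE)

  drop <- a$outlier_exercise | a$outlier_calories | a$low_wear | a$no_wear_record
  kept <- activity %>%
    inner_join(select(a[!drop, , drop = FALSE], "participant_id", "date"),
               by = c("participant_id", "date"))
  message(sprintf("apply_exclusions: dropped %d of %d person-days (%s)",
                  sum(drop), nrow(a),
                  paste(sprintf("%s %d", ledger$reason, ledger$n), collapse = ", ")))
  list(activity = kept, exclusions = exclusions, ledger = ledger)
}
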