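#' Person-level pre/post change summary
#'
#' For each participant in the panel, the change is the post-half mean minus
#' the pre-half mean of the daily outcome; the summary reports the mean and
#' sample standard deviation of those changes and the number of participants
#' contributing both halves (SD is `NA` for a single participant).
#'
#' @param panel An analysis panel.
#' @param outcome `"exercise_minutes"` or `"active_calories"`.
#' @param stratum `"overall"`, `"female"` or `"male"`.
#' @return One-row tibble `label`, `window_type`, `outcome`, `stratum`,
#'   `mean_change`, `sd_change`, `n` (zero-row input yields `n = 0` with
#'   `NA` summaries, and a message).
#' @export
person_level_change <- function(panel,
                                outcome = c("exercise_minutes", "active_calories"),
                                stratum = c("overall", "female", "male")) {
  outcome <- match.arg(outcome)
  stratum <- match.arg(stratum)
  d <- panel
  lab <- if (nrow(panel)) as.character(panel$label[1]) else NA_character_
  wt <- if (nrow(panel)) as.character(panel$window_type[1]) else NA_character_
  if (stratum != "overall") d <- filter(d, .data$sex == stratum)
  if (nrow(d) == 0) {
    message(sprintf("person_level_change: empty stratum '%s'", stratum))
    return(tibble::tibble(label = lab, window_type = wt, outcome = outcome,
                          stratum = stratum, mean_change = NA_real_,
                          sd_change = NA_real_, n = 0L))
  }
  delta <- d %>%
    summarise(pre = mean(.data[[outcome]][.data$post == 0L]),
              post_m = mean(.data[[outcome]][.data$post == 1L]),
              .by = "participant_id") %>%
    filter(is.finite(.data$pre), is.finite(.data$post_m)) %>%
    mutate(delta = .data$post_m - .data$pre)
  tibble::tibble(label = lab, window_type = wt, outcome = outcome,
                 stratum = stratum,
                 mean_change = mean(delta$delta),
                 sd_change = if (nrow(delta) > 1) sd(delta$delta) else NA_real_,
                 n = nrow(delta))
}

#' Change summaries over outcomes and strata
#'
#' @param panel An analysis panel.
#' @param strata Character vector of strata.
#' @param outcomes Character vector of outcomes.
#' @return Tibble, one row per outcome x stratum.
#' @export
change_summary_grid <- function(panel,
                                strata = c("overall", "female", "male"),
                                outcomes = c("exercise_minutes", "active_calories")) {
  purrr::map(outcomes, function(o) {
    purrr::map(strata, function(s) person_level_change(panel, o, s)) %>% bind_rows()
  }) %>% bind_rows()
}

#' Plot mean +/- SD person-level changes per transition
#'
#' Point-and-whisker display of the change summaries, panelled by outcome
#' and window type and coloured by stratum.
#'
#' @param changes Tibble of change summaries.
#' @return A ggplot object.
#' @export
plot_change_summaries <- function(changes) {
  ggplot2::ggplot(changes,
                  ggplot2::aes(x = .data$label, y = .data$mean_change,
                               colour = .data$stratum)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_change - .data$sd_change,
                                          ymax = .data$mean_change + .data$sd_change),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_grid(outcome ~ window_type, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "change in mean daily outcome (post - pre)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
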