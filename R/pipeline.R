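#' Analysis configuration
#'
#' Every operational threshold of the pipeline as a named key with its
#' standard value as default.
#'
#' @param ... Named overrides; unknown keys are an error.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    gap_threshold_minutes = 40,
    min_wear_minutes = 600,
    outlier_prob = 0.999,
    completeness_days = 7,
    sensitivity_completeness = c(1, 4, 5, 6),
    windows = c("treatment", "control"),
    strata = c("overall", "female", "male"),
    adjust = c(FALSE, TRUE),
    outcomes = c("exercise_minutes", "active_calories"),
    nodes = 11,
    run_sensitivity = TRUE
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      stop(sprintf("analysis_config: unknown config key(s): %s",
                   paste(bad, collapse = ", ")))
    }
    cfg[names(over)] <- over
  }
  structure(cfg, class = "analysis_config")
}

fit_panel_cells <- function(panels, cfg) {
  grid <- tidyr::expand_grid(i = seq_along(panels),
                             outcome = cfg$outcomes,
                             stratum = cfg$strata,
                             adjusted = cfg$adjust)
  purrr::pmap(grid, function(i, outcome, stratum, adjusted) {
    panel <- panels[[i]]
    res <- tryCatch(
      as_model_result(fit_nb_glmm(panel, outcome, adjust_weekday = adjusted,
                                  stratum = stratum, nodes = cfg$nodes)),
      error = function(e) {
        tibble::tibble(label = as.character(panel$label[1]),
                       window_type = as.character(panel$window_type[1]),
                       outcome = outcome, stratum = stratum,
                       adjusted = adjusted, n_participants = 0L, n_days = 0L,
                       rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       log_rr = NA_real_, se_log_rr = NA_real_,
                       alpha = NA_real_, sigma_b = NA_real_,
                       loglik = NA_real_, converged = FALSE)
      })
    res
  }) %>% bind_rows()
}

#' Run the full transition-effect analysis
#'
#' Orchestrates every stage: wear-time estimation, person-day filters,
#' day-level version assignment, transition detection and eligibility,
#' treatment and control panel construction, descriptive change summaries,
#' and one NB mixed model per transition label x window x outcome x stratum
#' x adjustment. Sensitivity reruns repeat the descriptives at completeness
#' thresholds 1, 4, 5 and 6 days and the models at threshold 1. Empty cells
#' are reported as non-converged rows, never fatal.
#'
#' @param records Heart-rate records tibble.
#' @param activity Daily activity tibble.
#' @param participants Participant metadata tibble.
#' @param config An [analysis_config()].
#' @return List with `results`, `change_summaries`, `sensitivity_results`,
#'   `sensitivity_changes`, `transitions` (assessed events),
#'   `exclusion_ledger` (transition reasons), `day_exclusions` (person-day
#'   filter output), `wear`, `thresholds`, and `panels`.
#' @export
run_full_analysis <- function(records, activity, participants,
                              config = analysis_config()) {
  cfg <- config
  wear <- estimate_daily_wear(records, activity,
                              gap_threshold_minutes = cfg$gap_threshold_minutes,
                              valid_wear_minutes = cfg$min_wear_minutes)
  thresholds <- percentile_thresholds(activity, participants,
                                      prob = cfg$outlier_prob)
  filt <- apply_exclusions(activity, wear, thresholds, participants,
                           min_wear_minutes = cfg$min_wear_minutes)
  act <- filt$activity

  day_versions <- assign_day_versions(records)
  events <- bind_rows(
    detect_transitions(count_day_versions(records, "software"), "software"),
    detect_transitions(count_day_versions(records, "hardware"), "hardware")
  )
  events <- assess_eligibility(events, day_versions, act)
  message(sprintf("run_full_analysis: %d events detected, %d eligible",
                  nrow(events), sum(events$eligible)))

  make_panels <- function(completeness) {
    out <- list()
    for (w in cfg$windows) {
      pan <- build_panels(events, act, participants,
                          completeness_days = completeness, window_type = w)
      for (lab in unique(pan$label)) {
        out[[paste(lab, w, completeness)]] <- filter(pan, .data$label == lab)
      }
    }
    out
  }

  panels <- make_panels(cfg$completeness_days)
  results <- if (length(panels)) fit_panel_cells(panels, cfg) else tibble::tibble()
  changes <- purrr::map(panels, function(p) {
    change_summary_grid(p, strata = cfg$strata, outcomes = cfg$outcomes)
  }) %>% bind_rows()

  sens_results <- tibble::tibble()
  sens_changes <- tibble::tibble()
  if (isTRUE(cfg$run_sensitivity)) {
    for (k in cfg$sensitivity_completeness) {
      pans_k <- make_panels(k)
      sens_changes <- bind_rows(
        sens_changes,
        purrr::map(pans_k, function(p) {
          change_summary_grid(p, strata = cfg$strata, outcomes = cfg$outcomes)
        }) %>% bind_rows() %>% mutate(completeness_days = k))
      if (k == min(cfg$sensitivity_completeness) && length(pans_k)) {
        sens_results <- fit_panel_cells(pans_k, cfg) %>%
          mutate(completeness_days = k)
      }
    }
  }

  list(results = results, change_summaries = changes,
       sensitivity_results = sens_results, sensitivity_changes = sens_changes,
       transitions = events, exclusion_ledger = exclusion_ledger(events),
       day_exclusions = filt, wear = wear, thresholds = thresholds,
       panels = panels)
}

#' Pivot tidy results into the headline-table layout
#'
#' One row per transition label and window type, columns
#' `<stratum>_<unadjusted|adjusted>` holding rendered `RR (95% CI)` cells,
#' for a single outcome.
#'
#' @param results Tidy results tibble.
#' @param outcome Outcome to display.
#' @return A wide tibble.
#' @export
format_results_wide <- function(results, outcome = "exercise_minutes") {
  results %>%
    filter(.data$outcome == !!outcome) %>%
    mutate(cell = render_rr_cell(.data$rr, .data$ci_low, .data$ci_high),
           col = paste0(.data$stratum, "_",
                        if_else(.data$adjusted, "adjusted", "unadjusted"))) %>%
    select("label", "window_type", "col", "cell") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "cell")
}
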