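# Builders for small in-code fixtures, and an independent brute-force
# minute-grid oracle for daily non-wear time.

hr_record <- function(participant_id, timestamp, bpm = 70,
                      source_version = "7.0.1", product_type = "Watch6,1") {
  tibble::tibble(participant_id = participant_id,
                 timestamp = as.POSIXct(timestamp, tz = "UTC"),
                 bpm = bpm, source_version = source_version,
                 product_type = product_type)
}

# heart-rate stream at given minutes-from-midnight offsets of one date
hr_at_minutes <- function(participant_id, date, minutes, ...) {
  hr_record(participant_id,
            midnight_of_date(as.Date(date)) + minutes * 60, ...)
}

midnight_of_date <- function(date) {
  as.POSIXct(as.numeric(as.Date(date)) * 86400, origin = "1970-01-01", tz = "UTC")
}

# Brute-force oracle: mark every whole minute of the grid that lies fully
# inside an inter-measurement interval of >= threshold minutes (range
# boundaries act as virtual measurements). times_min are minutes from
# midnight of the first date; returns per-day non-wear minutes.
oracle_daily_nonwear <- function(times_min, n_days, threshold) {
  bounds <- c(0, sort(times_min), n_days * 1440)
  lo <- utils::head(bounds, -1)
  hi <- utils::tail(bounds, -1)
  keep <- (hi - lo) >= threshold
  vapply(seq_len(n_days), function(day) {
    mins <- (day - 1) * 1440 + 0:1439
    marked <- rep(FALSE, 1440)
    for (g in which(keep)) {
      marked <- marked | (mins >= lo[g] & (mins + 1) <= hi[g])
    }
    sum(marked)
  }, numeric(1))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

wd_of <- function(date) {
  lv <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  factor(lv[as.integer(format(date, "%u"))], levels = lv)
}

toy_cached <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_worked_toy()
    val
  }
})
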