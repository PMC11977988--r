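#' Load the hardware index
#'
#' The index maps internal product identifiers (e.g. `"Watch6,2"`) to the
#' marketing generation (e.g. `"Series 6"`). All size and cellular variants
#' of one generation map to the same name. It ships as an editable CSV since
#' the vendor extends the product line annually.
#'
#' @param path CSV with columns `product_type`, `commercial_name`; defaults
#'   to the bundled table.
#' @return Tibble `product_type`, `commercial_name`.
#' @export
load_hardware_index <- function(path = system.file("extdata", "hardware_index.csv",
                                                   package = "wearversion")) {
  idx <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  require_columns(idx, c("product_type", "commercial_name"), path)
  if (anyDuplicated(idx$product_type)) {
    stop("hardware index: each product_type must map to exactly one name")
  }
  idx
}

#' Parse the major software version from a raw version string
#'
#' Measurement behaviour is assumed to change only between major releases,
#' so the version is reduced to the integer before the first dot
#' (`"7.3.1"` -> 7); minor updates are ignored. A non-numeric leading token
#' yields `NA` (the record is excluded and counted by callers).
#'
#' @param source_version Character vector of raw version strings.
#' @return Integer vector of major versions, `NA` where unparseable.
#' @export
parse_major_version <- function(source_version) {
  lead <- sub("\\..*$", "", source_version)
  ok <- grepl("^[0-9]+$", lead)
  out <- rep(NA_integer_, length(source_version))
  out[ok] <- as.integer(lead[ok])
  out
}

#' Map product identifiers to commercial hardware names
#'
#' @param product_type Character vector of raw identifiers.
#' @param index Hardware index from [load_hardware_index()].
#' @return Character vector of commercial names; unknown identifiers map to
#'   the sentinel `"unknown"` (such days are excluded from hardware
#'   analysis).
#' @export
map_hardware <- function(product_type, index = load_hardware_index()) {
  m <- index$commercial_name[match(product_type, index$product_type)]
  if_else(is.na(m), "unknown", m)
}

#' Per-day measurement counts by version
#'
#' The day-level building block for version assignment and transition-date
#' detection: how many of a participant-day's heart-rate measurements carry
#' each software major version (or hardware name).
#'
#' @param records Heart-rate records tibble.
#' @param kind `"software"` or `"hardware"`.
#' @param index Hardware index (hardware kind only).
#' @return Tibble `participant_id`, `date`, `version` (character), `n`.
#'   Unparseable software versions and unknown hardware are dropped (with a
#'   message giving the count).
#' @export
count_day_versions <- function(records, kind = c("software", "hardware"),
                               index = load_hardware_index()) {
  kind <- match.arg(kind)
  d <- tibble::tibble(
    participant_id = records$participant_id,
    date = as.Date(records$timestamp, tz = "UTC"),
    version = if (kind == "software") {
      as.character(parse_major_version(records$source_version))
    } else {
      map_hardware(records$product_type, index)
    }
  )
  bad <- if (kind == "software") is.na(d$version) else d$version == "unknown"
  if (any(bad)) {
    message(sprintf("count_day_versions(%s): dropped %d records with %s version",
                    kind, sum(bad), if (kind == "software") "unparseable" else "unknown"))
  }
  d[!bad, , drop = FALSE] %>%
    count(.data$participant_id, .data$date, .data$version, name = "n")
}

#' Rank hardware names by first appearance per participant
#'
#' Hardware generations are not totally ordered across product lines, so the
#' "newer" device for tie-breaking is the one first seen later in that
#' participant's record stream.
#'
#' @param records Heart-rate records tibble.
#' @param index Hardware index.
#' @return Tibble `participant_id`, `version`, `rank` (higher = newer).
#' @export
hardware_first_seen_rank <- function(records, index = load_hardware_index()) {
  tibble::tibble(participant_id = records$participant_id,
                 timestamp = records$timestamp,
                 version = map_hardware(records$product_type, index)) %>%
    filter(.data$version != "unknown") %>%
    summarise(first_seen = min(.data$timestamp),
              .by = c("participant_id", "version")) %>%
    arrange(.data$participant_id, .data$first_seen) %>%
    mutate(rank = row_number(), .by = "participant_id") %>%
    select("participant_id", "version", "rank")
}

#' Assign one software and one hardware version per participant-day
#'
#' The day-level version is the mode of that day's measurements. Ties break
#' toward the newer version: numerically for software, by later first
#' appearance for hardware (upgrades are monotone in time, so on the cusp
#' day the new version is taken as operative).
#'
#' @param records Heart-rate records tibble.
#' @param index Hardware index.
#' @return Tibble `participant_id`, `date`, `n_measurements`,
#'   `major_software` (integer), `software_share`, `hardware_name`,
#'   `hardware_share`. Shares are the winning version's fraction of the
#'   day's measurements (of parseable/known ones for its kind); hardware is
#'   `NA` on days with only unknown identifiers.
#' @export
assign_day_versions <- function(records, index = load_hardware_index()) {
  sw <- count_day_versions(records, "software", index)
  hw <- count_day_versions(records, "hardware", index)
  hw_rank <- hardware_first_seen_rank(records, index)

  sw_mode <- sw %>%
    mutate(total = sum(.data$n), .by = c("participant_id", "date")) %>%
    mutate(rank = as.integer(.data$version)) %>%
    arrange(.data$participant_id, .data$date, dplyr::desc(.data$n),
            dplyr::desc(.data$rank)) %>%
    slice_head(n = 1, by = c("participant_id", "date")) %>%
    transmute(.data$participant_id, .data$date,
              major_software = as.integer(.data$version),
              software_share = .data$n / .data$total,
              n_sw = .data$total)

  hw_mode <- hw %>%
    mutate(total = sum(.data$n), .by = c("participant_id", "date")) %>%
    left_join(hw_rank, by = c("participant_id", "version")) %>%
    arrange(.data$participant_id, .data$date, dplyr::desc(.data$n),
            dplyr::desc(.data$rank)) %>%
    slice_head(n = 1, by = c("participant_id", "date")) %>%
    transmute(.data$participant_id, .data$date,
              hardware_name = .data$version,
              hardware_share = .data$n / .data$total)

  n_day <- records %>%
    mutate(date = as.Date(.data$timestamp, tz = "UTC")) %>%
    count(.data$participant_id, .data$date, name = "n_measurements")

  n_day %>%
    left_join(sw_mode, by = c("participant_id", "date")) %>%
    left_join(hw_mode, by = c("participant_id", "date")) %>%
    select(-"n_sw") %>%
    arrange(.data$participant_id, .data$date)
}
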