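# Event-log I/O: long-format CSV, one file per person.
# Columns: timestamp,person_id,channel_id,sensor_type,field,value
# Timestamps are ISO-8601 wall clock with millisecond resolution; multi-field
# payloads (tilt x/y/z, temp/rh, x/y) occupy one row per field at the same
# instant.

#' Write a sensor event log to CSV
#'
#' @param events Event tibble as produced by [simulate_person_day()] /
#'   [read_event_log()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  out <- tibble(
    timestamp = format_ts(events$timestamp),
    person_id = events$person_id,
    channel_id = events$channel_id,
    sensor_type = events$sensor_type,
    field = events$field,
    value = events$value
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sensor event log
#'
#' Parses the long-format event CSV, sorts by timestamp, and reports
#' malformed lines (wrong field count or non-numeric value) with their line
#' numbers as a warning while keeping the valid rows. An unparseable
#' timestamp in an otherwise well-formed row is a hard error; events on
#' channels outside `roster` (when given) are skipped with a warning.
#'
#' @param path Path to a CSV written by [write_event_log()].
#' @param roster Optional character vector of known channel ids.
#' @return Time-sorted event tibble.
#' @export
read_event_log <- function(path, roster = NULL) {
  if (!file.exists(path)) abort(paste0("no such event log: ", path))
  lines <- readLines(path)
  if (!length(lines)) abort("event log has no header line")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  expected <- c("timestamp", "person_id", "channel_id", "sensor_type", "field", "value")
  if (!identical(header, expected)) abort("event log header does not match the schema")
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(tibble(
      timestamp = ts_of(numeric()), person_id = character(),
      channel_id = character(), sensor_type = character(),
      field = character(), value = numeric()
    ))
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  bad_shape <- nf != 6
  vals <- suppressWarnings(as.numeric(vapply(
    parts, function(x) if (length(x) == 6) x[6] else NA_character_, ""
  )))
  bad_value <- !bad_shape & is.na(vals)
  bad <- bad_shape | bad_value
  if (any(bad)) {
    warn(paste0(
      "skipping ", sum(bad), " malformed event line(s): ",
      paste(which(bad) + 1, collapse = ", ")
    ))
  }
  keep <- which(!bad)
  m <- do.call(rbind, parts[keep])
  ts <- parse_ts(m[, 1])
  if (anyNA(ts)) {
    abort(paste0(
      "unparseable timestamp at line(s): ",
      paste(keep[is.na(ts)] + 1, collapse = ", ")
    ))
  }
  ev <- tibble(
    timestamp = ts, person_id = m[, 2], channel_id = m[, 3],
    sensor_type = m[, 4], field = m[, 5], value = vals[keep]
  )
  if (!is.null(roster)) {
    unknown <- !ev$channel_id %in% roster
    if (any(unknown)) {
      warn(paste0(
        "skipping ", sum(unknown), " event(s) on unknown channel(s): ",
        paste(unique(ev$channel_id[unknown]), collapse = ", ")
      ))
      ev <- ev[!unknown, , drop = FALSE]
    }
  }
  arrange(ev, .data$timestamp, .data$channel_id, .data$field)
}

#' Per-channel daily event counts
#'
#' Summarises an event stream as one row per day and one column per channel,
#' counting event instants (multi-field payload rows at the same instant
#' count once) — the day-level sheet layout used for raw-data inspection.
#'
#' @param events Event tibble.
#' @return Wide tibble: `date`, then one integer column per channel.
#' @export
summary_report <- function(events) {
  if (!nrow(events)) {
    return(tibble(date = as.Date(character())))
  }
  inst <- distinct(events, .data$timestamp, .data$channel_id)
  inst$date <- as.Date(inst$timestamp, tz = TZ)
  counts <- dplyr::count(inst, .data$date, .data$channel_id)
  tidyr::pivot_wider(
    counts,
    names_from = "channel_id", values_from = "n", values_fill = 0L,
    names_sort = TRUE
  )
}
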