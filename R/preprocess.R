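# Stage-2 preprocessing: per-sensor conversions from raw measurements to use
# episodes, time-binned count/duration series, and lidar kinematics.

# single-field numeric series (t, v) for one channel
field_series <- function(events, field) {
  e <- events[events$field == field, , drop = FALSE]
  list(t = as.numeric(e$timestamp), v = e$value)
}

#' Vibration tilt stream to use episodes
#'
#' A use opens when the sensor's tilt deviates from its resting pose by more
#' than `tilt_tol_deg` and closes when the tilt returns within tolerance; the
#' restore time is the use duration. Episodes with no restore are truncated
#' at `timeout_s`. The resting pose is the componentwise median tilt vector
#' of the stream — uses are transient, so the sensor rests in its mounted
#' pose most of the time and the median is robust to a stream that happens
#' to begin mid-use.
#'
#' @param events Events of one vibration channel (fields `tilt_x/y/z`).
#' @param tilt_tol_deg Angular tolerance in degrees (default 10).
#' @param timeout_s Restore timeout in seconds (default 600).
#' @return Episode tibble (`channel_id`, `start`, `end`, `kind`).
#' @export
vibration_use_episodes <- function(events, tilt_tol_deg = 10, timeout_s = 600) {
  if (!nrow(events)) return(empty_episodes())
  e <- events[events$field %in% c("tilt_x", "tilt_y", "tilt_z"), , drop = FALSE]
  tt <- sort(unique(as.numeric(e$timestamp)))
  if (length(tt) < 2) return(empty_episodes())
  m <- matrix(NA_real_, length(tt), 3,
    dimnames = list(NULL, c("tilt_x", "tilt_y", "tilt_z"))
  )
  m[cbind(
    match(as.numeric(e$timestamp), tt),
    match(e$field, colnames(m))
  )] <- e$value
  m[is.na(m)] <- 0
  w <- tibble(timestamp = ts_of(tt))
  rest <- apply(m, 2, median)
  if (sqrt(sum(rest^2)) < 1e-6) rest <- m[1, ]
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  cosang <- (m %*% rest) / (nrm * sqrt(sum(rest^2)))
  ang <- acos(clamp(as.numeric(cosang), -1, 1)) * 180 / pi
  dev <- ang > tilt_tol_deg
  t <- as.numeric(w$timestamp)
  starts <- which(dev & !c(FALSE, dev[-length(dev)]))
  if (!length(starts)) return(empty_episodes())
  ends <- vapply(starts, function(i) {
    j <- which(!dev & seq_along(dev) > i)
    restore <- if (length(j)) t[min(j)] else Inf
    min(restore, t[i] + timeout_s)
  }, numeric(1))
  tibble(
    channel_id = events$channel_id[1], start = ts_of(t[starts]),
    end = ts_of(ends), kind = "tilt_use"
  )
}

#' Smart-plug power series to on-intervals
#'
#' Intervals where measured power is at or above `on_threshold_w`, treating
#' the samples as a right-continuous step function. Off-gaps shorter than
#' `debounce_s` are merged. An interval still on at the last sample is closed
#' at `end_time` (default: the last sample's time).
#'
#' @param events Events of one plug channel (field `power_w`).
#' @param on_threshold_w On threshold in watts (default 5).
#' @param debounce_s Merge gaps shorter than this many seconds (default 60).
#' @param end_time Optional stream end used to close a dangling on-interval.
#' @return Episode tibble with kind `plug_on`.
#' @export
plug_on_intervals <- function(events, on_threshold_w = 5, debounce_s = 60,
                              end_time = NULL) {
  if (on_threshold_w < 0) stop_config("on_threshold_w must be >= 0")
  s <- field_series(events, "power_w")
  if (!length(s$t)) return(empty_episodes())
  o <- order(s$t)
  t <- s$t[o]
  on <- s$v[o] >= on_threshold_w
  t_end <- if (is.null(end_time)) max(t) else as.numeric(end_time)
  starts <- which(on & !c(FALSE, on[-length(on)]))
  if (!length(starts)) return(empty_episodes())
  ends <- vapply(starts, function(i) {
    j <- which(!on & seq_along(on) > i)
    if (length(j)) t[min(j)] else t_end
  }, numeric(1))
  iv <- tibble(start = t[starts], end = pmax(ends, t[starts]))
  # debounce: merge near-adjacent intervals
  if (nrow(iv) > 1) {
    keep_start <- iv$start[1]
    merged <- list()
    cur_end <- iv$end[1]
    for (i in 2:nrow(iv)) {
      if (iv$start[i] - cur_end < debounce_s) {
        cur_end <- max(cur_end, iv$end[i])
      } else {
        merged[[length(merged) + 1]] <- c(keep_start, cur_end)
        keep_start <- iv$start[i]
        cur_end <- iv$end[i]
      }
    }
    merged[[length(merged) + 1]] <- c(keep_start, cur_end)
    m <- do.call(rbind, merged)
    iv <- tibble(start = m[, 1], end = m[, 2])
  }
  tibble(
    channel_id = events$channel_id[1], start = ts_of(iv$start),
    end = ts_of(iv$end), kind = "plug_on"
  )
}

#' Temperature series to rise episodes
#'
#' An episode opens when the temperature exceeds a rolling baseline (median
#' of out-of-episode samples in the trailing `baseline_window_s`) by at least
#' `delta_c`, and closes when it falls back within `delta_c / 2` of the
#' baseline frozen at episode start. Used to detect gas-stove use and
#' showers.
#'
#' @param events Events of one temperature-humidity channel (field `temp_c`).
#' @param delta_c Rise threshold in degrees Celsius (default 2).
#' @param baseline_window_s Trailing window for the rolling baseline.
#' @return Episode tibble with kind `temp_rise`.
#' @export
temp_rise_episodes <- function(events, delta_c = 2, baseline_window_s = 3600) {
  s <- field_series(events, "temp_c")
  if (length(s$t) < 2) return(empty_episodes())
  o <- order(s$t)
  t <- s$t[o]
  v <- s$v[o]
  n <- length(t)
  in_ep <- FALSE
  base_idx <- integer()
  ep_base <- NA_real_
  ep_start <- NA_real_
  starts <- numeric()
  ends <- numeric()
  for (i in seq_len(n)) {
    base_idx <- base_idx[t[base_idx] > t[i] - baseline_window_s]
    baseline <- if (length(base_idx)) median(v[base_idx]) else v[i]
    if (!in_ep) {
      if (v[i] - baseline >= delta_c) {
        in_ep <- TRUE
        ep_base <- baseline
        ep_start <- t[i]
      } else {
        base_idx <- c(base_idx, i)
      }
    } else if (v[i] <= ep_base + delta_c / 2) {
      in_ep <- FALSE
      starts <- c(starts, ep_start)
      ends <- c(ends, t[i])
      base_idx <- c(base_idx, i)
    }
  }
  if (in_ep) {
    starts <- c(starts, ep_start)
    ends <- c(ends, t[n])
  }
  if (!length(starts)) return(empty_episodes())
  tibble(
    channel_id = events$channel_id[1], start = ts_of(starts),
    end = ts_of(ends), kind = "temp_rise"
  )
}

#' Door state stream to open episodes
#'
#' One episode per open (state 1) to close (state 0) pair; a door still open
#' at the stream end closes there.
#'
#' @param events Events of one door channel (field `state`).
#' @return Episode tibble with kind `door_open`.
#' @export
door_open_episodes <- function(events) {
  s <- field_series(events, "state")
  if (!length(s$t)) return(empty_episodes())
  o <- order(s$t)
  t <- s$t[o]
  open <- s$v[o] > 0.5
  starts <- which(open & !c(FALSE, open[-length(open)]))
  if (!length(starts)) return(empty_episodes())
  ends <- vapply(starts, function(i) {
    j <- which(!open & seq_along(open) > i)
    if (length(j)) t[min(j)] else t[length(t)]
  }, numeric(1))
  tibble(
    channel_id = events$channel_id[1], start = ts_of(t[starts]),
    end = ts_of(pmax(ends, t[starts])), kind = "door_open"
  )
}

#' Motion detections to active bouts
#'
#' Clusters successive detections separated by less than `gap_s` into one
#' active bout; each bout is held `hold_s` seconds past its last detection
#' (the sensor's nominal hold time), giving motion its duration series.
#'
#' @param events Events of one motion channel (field `detected`).
#' @param gap_s Gap that splits bouts (default 120 s).
#' @param hold_s Hold time appended to each bout (default 60 s).
#' @return Episode tibble with kind `motion_active`.
#' @export
motion_active_bouts <- function(events, gap_s = 120, hold_s = 60) {
  s <- field_series(events, "detected")
  if (!length(s$t)) return(empty_episodes())
  t <- sort(s$t)
  grp <- cumsum(c(1, diff(t) >= gap_s))
  starts <- tapply(t, grp, min)
  ends <- tapply(t, grp, max) + hold_s
  tibble(
    channel_id = events$channel_id[1], start = ts_of(as.numeric(starts)),
    end = ts_of(as.numeric(ends)), kind = "motion_active"
  )
}

#' Bin episodes or point events into count/duration series
#'
#' Bins are half-open `[start, start + width)`, labeled by their start. An
#' episode contributes count 1 to the bin containing its start and its
#' overlap duration to every bin it spans, so per-bin durations never exceed
#' the bin width and sum to the episode's total time. Zero-length episodes
#' are point events and contribute counts only.
#'
#' @param episodes Episode tibble (`channel_id`, `start`, `end`).
#' @param bin_width `"10 min"`, `"1 hour"`, `"1 day"`, or a width in seconds.
#' @param origin,end Optional grid bounds (instants); defaults to the
#'   episodes' span.
#' @param complete If `TRUE`, emit every grid bin for every channel
#'   (zero-filled); otherwise only bins touched by an episode.
#' @return Tibble: `channel_id`, `bin_start`, `count`, `duration_s`.
#' @export
bin_counts_durations <- function(episodes, bin_width = "1 hour", origin = NULL,
                                 end = NULL, complete = FALSE) {
  w <- bin_width_seconds(bin_width)
  if (!nrow(episodes)) {
    return(tibble(
      channel_id = character(), bin_start = ts_of(numeric()),
      count = integer(), duration_s = numeric()
    ))
  }
  s <- as.numeric(episodes$start)
  e <- pmax(as.numeric(episodes$end), s)
  if (any(e < s)) stop_config("episode end precedes start")
  g0 <- if (is.null(origin)) floor_bin(min(s), w) else floor_bin(as.numeric(origin), w)
  g1 <- if (is.null(end)) floor_bin(max(e) + w - 1e-6, w) else floor_bin(as.numeric(end) - 1e-3, w) + w
  # counts at start bins
  cnt <- tibble(channel_id = episodes$channel_id, bin_start = floor_bin(s, w)) |>
    dplyr::count(.data$channel_id, .data$bin_start, name = "count")
  # durations over all spanned bins
  b0 <- floor_bin(s, w)
  b1 <- floor_bin(ifelse(e > s, e - 1e-3, s), w)
  nb <- pmax(1, (b1 - b0) / w + 1)
  idx <- rep(seq_along(s), nb)
  off <- unlist(lapply(nb, seq_len)) - 1
  bins <- b0[idx] + off * w
  dur <- overlap_s(s[idx], e[idx], bins, bins + w)
  dtab <- tibble(
    channel_id = episodes$channel_id[idx], bin_start = bins,
    duration_s = dur
  ) |>
    group_by(.data$channel_id, .data$bin_start) |>
    summarise(duration_s = sum(.data$duration_s), .groups = "drop")
  out <- dplyr::full_join(cnt, dtab, by = c("channel_id", "bin_start")) |>
    mutate(
      count = as.integer(dplyr::coalesce(.data$count, 0L)),
      duration_s = dplyr::coalesce(.data$duration_s, 0)
    )
  if (complete) {
    grid <- expand.grid(
      channel_id = unique(episodes$channel_id),
      bin_start = seq(g0, g1 - w, by = w), stringsAsFactors = FALSE
    )
    out <- dplyr::left_join(as_tibble(grid), out, by = c("channel_id", "bin_start")) |>
      mutate(
        count = as.integer(dplyr::coalesce(.data$count, 0L)),
        duration_s = dplyr::coalesce(.data$duration_s, 0)
      )
  }
  out <- out[out$bin_start >= g0 & out$bin_start < g1, , drop = FALSE]
  out$bin_start <- ts_of(out$bin_start)
  arrange(out, .data$channel_id, .data$bin_start)
}

# preprocessing thresholds, overridable through the run config
default_thresholds <- function() {
  list(
    tilt_tol_deg = 10, tilt_timeout_s = 600,
    plug_on_w = 5, plug_debounce_s = 60,
    temp_delta_c = 2, temp_baseline_window_s = 3600,
    motion_gap_s = 120, motion_hold_s = 60,
    gait_min_speed_kmh = 0.6, zone_min_dwell_s = 5,
    cooking_window_min = 30, dishes_min_s = 30,
    outing_quiet_gap_min = 10, outing_resume_min = 5
  )
}

#' Convert one person's events into per-channel use episodes
#'
#' Applies the sensor-type-specific conversion to every channel: door open
#' episodes, vibration use episodes, plug on-intervals, temperature rises,
#' and motion active bouts. Lidar events are excluded (see
#' [lidar_kinematics()]).
#'
#' @param events Event tibble for one person.
#' @param thresholds Named list as [default_thresholds()].
#' @return Episode tibble across channels, with `kind` per sensor rule.
#' @export
channel_episodes <- function(events, thresholds = default_thresholds()) {
  th <- modifyList(default_thresholds(), thresholds)
  ev <- events[events$sensor_type != "lidar", , drop = FALSE]
  if (!nrow(ev)) return(empty_episodes())
  end_time <- max(ev$timestamp)
  parts <- lapply(split(ev, ev$channel_id), function(ch) {
    switch(ch$sensor_type[1],
      door = door_open_episodes(ch),
      vibration = vibration_use_episodes(ch, th$tilt_tol_deg, th$tilt_timeout_s),
      plug = plug_on_intervals(ch, th$plug_on_w, th$plug_debounce_s, end_time),
      temp_humidity = temp_rise_episodes(ch, th$temp_delta_c, th$temp_baseline_window_s),
      motion = motion_active_bouts(ch, th$motion_gap_s, th$motion_hold_s),
      empty_episodes()
    )
  })
  arrange(bind_rows(parts), .data$start)
}

#' Time-binned count/duration series for all channels of one person
#'
#' Counts follow the sensor's natural event unit (door openings, motion
#' detections, vibration uses, plug on-intervals, temperature rises);
#' durations come from the corresponding episodes. Motion counts are raw
#' detections while motion durations come from active bouts.
#'
#' @param events Event tibble for one person.
#' @param bin_width Bin width as in [bin_counts_durations()].
#' @param thresholds Named list as [default_thresholds()].
#' @param origin,end Optional grid bounds.
#' @param episodes Optional precomputed [channel_episodes()] output (avoids
#'   recomputation when shared with the ADL stage).
#' @return Tibble: `person_id`, `channel_id`, `bin_start`, `count`,
#'   `duration_s`.
#' @export
binned_series <- function(events, bin_width = "1 hour",
                          thresholds = default_thresholds(),
                          origin = NULL, end = NULL, episodes = NULL) {
  eps <- episodes %||% channel_episodes(events, thresholds)
  out <- bin_counts_durations(eps, bin_width, origin, end)
  # motion counts are detection hits, not bout counts
  mo <- events[events$sensor_type == "motion" & events$field == "detected", , drop = FALSE]
  if (nrow(mo)) {
    pts <- tibble(
      channel_id = mo$channel_id, start = mo$timestamp, end = mo$timestamp
    )
    mcnt <- bin_counts_durations(pts, bin_width, origin, end)
    mdur <- out[out$channel_id %in% unique(mo$channel_id), c("channel_id", "bin_start", "duration_s")]
    out <- out[!out$channel_id %in% unique(mo$channel_id), , drop = FALSE]
    mo_all <- dplyr::full_join(
      mcnt[, c("channel_id", "bin_start", "count")], mdur,
      by = c("channel_id", "bin_start")
    ) |>
      mutate(
        count = as.integer(dplyr::coalesce(.data$count, 0L)),
        duration_s = dplyr::coalesce(.data$duration_s, 0)
      )
    out <- bind_rows(out, mo_all)
  }
  out$person_id <- if (nrow(events)) events$person_id[1] else character(0)
  arrange(
    out[, c("person_id", "channel_id", "bin_start", "count", "duration_s")],
    .data$channel_id, .data$bin_start
  )
}

#' Lidar track to gait samples and movement distance
#'
#' Speeds are finite differences of consecutive positions converted to km/h.
#' Samples below `min_speed_kmh` are excluded from gait statistics
#' (`is_gait = FALSE`) but their displacement still accrues to movement
#' distance. Pairs separated by more than `track_gap_s` are tracking
#' discontinuities (the body left the sensor's view) and contribute neither
#' gait nor displacement. Duplicate timestamps are skipped with a warning.
#'
#' @param track Tibble `timestamp`, `x`, `y` (time-sorted or sortable).
#' @param min_speed_kmh Gait floor in km/h (default 0.6).
#' @param track_gap_s Maximum inter-sample gap within one tracking session
#'   (default 300 s).
#' @return Tibble: `timestamp`, `speed_kmh`, `displacement_m`, `is_gait`.
#' @export
lidar_kinematics <- function(track, min_speed_kmh = 0.6, track_gap_s = 300) {
  track <- arrange(as_tibble(track), .data$timestamp)
  t <- as.numeric(track$timestamp)
  if (length(t) < 2) {
    return(tibble(
      timestamp = ts_of(numeric()), speed_kmh = numeric(),
      displacement_m = numeric(), is_gait = logical()
    ))
  }
  dt <- diff(t)
  dup <- dt <= 0
  if (any(dup)) warn(paste0("skipping ", sum(dup), " duplicate-timestamp lidar pair(s)"))
  disp <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  keep <- !dup & dt <= track_gap_s
  speed <- disp[keep] / dt[keep] * 3.6
  tibble(
    timestamp = ts_of(t[-1][keep]), speed_kmh = speed,
    displacement_m = disp[keep], is_gait = speed >= min_speed_kmh
  )
}

# extract the (t, x, y) track of the lidar channel from an event stream
lidar_track <- function(events, lidar_channel = "lidar1") {
  e <- events[events$channel_id == lidar_channel, , drop = FALSE]
  if (!nrow(e)) return(tibble(timestamp = ts_of(numeric()), x = numeric(), y = numeric()))
  tt <- sort(unique(as.numeric(e$timestamp)))
  m <- matrix(NA_real_, length(tt), 2, dimnames = list(NULL, c("x", "y")))
  m[cbind(match(as.numeric(e$timestamp), tt), match(e$field, c("x", "y")))] <- e$value
  tibble(timestamp = ts_of(tt), x = m[, "x"], y = m[, "y"])
}

# per-bin lidar features: total movement distance (m) and mean gait speed
# (km/h; 0 when no gait sample falls in the bin)
bin_lidar <- function(kin, bin_width = "1 hour", origin = NULL, end = NULL) {
  w <- bin_width_seconds(bin_width)
  if (!nrow(kin)) {
    return(tibble(bin_start = ts_of(numeric()), movement_distance_m = numeric(), gait_speed_kmh = numeric()))
  }
  b <- floor_bin(as.numeric(kin$timestamp), w)
  out <- tibble(bin_start = b, d = kin$displacement_m, s = kin$speed_kmh, g = kin$is_gait) |>
    group_by(.data$bin_start) |>
    summarise(
      movement_distance_m = sum(.data$d),
      gait_speed_kmh = if (any(.data$g)) mean(.data$s[.data$g]) else 0,
      .groups = "drop"
    )
  out$bin_start <- ts_of(out$bin_start)
  out
}

#' Zone visits from a lidar track
#'
#' Maximal runs of consecutive track points inside one zone become a visit.
#' Points outside every zone are assigned to the nearest zone (reported via
#' a message); visits shorter than `min_dwell_s` are discarded and their
#' neighbours merged when they share a zone.
#'
#' @param track Tibble `timestamp`, `x`, `y`.
#' @param zm A [zone_map()].
#' @param min_dwell_s Minimum dwell in seconds (default 5).
#' @return Tibble: `zone_id`, `start`, `end`.
#' @export
zone_visits <- function(track, zm, min_dwell_s = 5) {
  track <- arrange(as_tibble(track), .data$timestamp)
  if (!nrow(track)) {
    return(tibble(zone_id = integer(), start = ts_of(numeric()), end = ts_of(numeric())))
  }
  ids <- locate_zone(zm, track$x, track$y)
  if (attr(ids, "n_outside") > 0) {
    inform(paste0(attr(ids, "n_outside"), " track point(s) outside all zones assigned to nearest zone"))
  }
  t <- as.numeric(track$timestamp)
  r <- rle(as.integer(ids))
  endi <- cumsum(r$lengths)
  starti <- c(1, head(endi, -1) + 1)
  vis <- tibble(zone_id = r$values, start = t[starti], end = t[endi])
  vis <- vis[vis$end - vis$start >= min_dwell_s, , drop = FALSE]
  # merge neighbours that now share a zone
  if (nrow(vis) > 1) {
    keep <- logical(nrow(vis))
    merged <- vis[1, ]
    res <- list()
    for (i in 2:nrow(vis)) {
      if (vis$zone_id[i] == merged$zone_id) {
        merged$end <- vis$end[i]
      } else {
        res[[length(res) + 1]] <- merged
        merged <- vis[i, ]
      }
    }
    res[[length(res) + 1]] <- merged
    vis <- bind_rows(res)
  }
  tibble(zone_id = vis$zone_id, start = ts_of(vis$start), end = ts_of(vis$end))
}
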