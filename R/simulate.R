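# Persona-driven synthetic smart-home cohort generator.
#
# One simulated day is assembled from scheduled activities (sleep, grooming,
# meals, medications, outings, chores, TV/mat sessions, night awakenings)
# that emit raw sensor events on the household's channels: door state
# changes, motion hits with lux, vibration tilt samples (deviate/restore
# pairs), temperature traces, smart-plug power steps, and a 1 Hz lidar track
# along zone-to-zone paths at the persona's gait speed.

# --- low-level event emission ------------------------------------------------

new_event_sink <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e
}

emit <- function(sink, channel, sensor_type, t, field, value) {
  n <- max(length(t), length(field), length(value))
  sink$rows[[length(sink$rows) + 1]] <- list(
    t = rep_len(round(t, 3), n),
    channel_id = rep_len(channel, n),
    sensor_type = rep_len(sensor_type, n),
    field = rep_len(field, n),
    value = rep_len(value, n)
  )
  invisible(NULL)
}

collect_events <- function(sink, person_id) {
  if (!length(sink$rows)) {
    return(tibble(
      timestamp = ts_of(numeric()), person_id = character(),
      channel_id = character(), sensor_type = character(),
      field = character(), value = numeric()
    ))
  }
  df <- tibble(
    timestamp = ts_of(unlist(lapply(sink$rows, `[[`, "t"))),
    person_id = person_id,
    channel_id = unlist(lapply(sink$rows, `[[`, "channel_id")),
    sensor_type = unlist(lapply(sink$rows, `[[`, "sensor_type")),
    field = unlist(lapply(sink$rows, `[[`, "field")),
    value = unlist(lapply(sink$rows, `[[`, "value"))
  )
  arrange(df, .data$timestamp, .data$channel_id, .data$field)
}

# vibration use: tilt deviates at t, restores at t + dur (the restore time is
# the use duration)
em_vib_use <- function(sink, ch, t, dur) {
  ang <- runif(1, 20 * pi / 180, 60 * pi / 180)
  phi <- runif(1, 0, 2 * pi)
  emit(
    sink, ch, "vibration", rep(t, 3), c("tilt_x", "tilt_y", "tilt_z"),
    c(sin(ang) * cos(phi), sin(ang) * sin(phi), cos(ang))
  )
  emit(sink, ch, "vibration", rep(t + dur, 3), c("tilt_x", "tilt_y", "tilt_z"), c(0, 0, 1))
}

em_vib_rest <- function(sink, ch, t) {
  emit(sink, ch, "vibration", rep(t, 3), c("tilt_x", "tilt_y", "tilt_z"), c(0, 0, 1))
}

em_door <- function(sink, ch, t_open, t_close) {
  emit(sink, ch, "door", c(t_open, t_close), "state", c(1, 0))
}

em_plug <- function(sink, ch, t_on, t_off, watts) {
  emit(sink, ch, "plug", t_on, "power_w", watts)
  if (!is.null(t_off)) emit(sink, ch, "plug", t_off, "power_w", 0)
}

em_motion <- function(sink, ch, t) {
  if (!length(t)) return(invisible(NULL))
  h <- hour_of(t)
  lux <- ifelse(h >= 7 & h < 18, 250 + rnorm(length(t), 0, 50),
    ifelse(h >= 18 & h < 23, 120 + rnorm(length(t), 0, 25),
      10 + abs(rnorm(length(t), 0, 4))
    )
  )
  for (i in seq_along(t)) {
    emit(sink, ch, "motion", rep(t[i], 2), c("detected", "lux"), c(1, max(0, lux[i])))
  }
}

# temperature trace: ambient + cooking/shower rise with exponential decay
em_temp_profile <- function(sink, ch, t_start, dur, ambient, rise) {
  ts <- seq(t_start, t_start + dur + 900, by = 60)
  rel <- ts - t_start
  temp <- ambient +
    ifelse(rel <= dur, rise * pmin(1, rel / 180), rise * exp(-(rel - dur) / 300)) +
    rnorm(length(ts), 0, 0.1)
  rh <- 45 + rnorm(length(ts), 0, 2) + ifelse(rel <= dur, 8, 0)
  for (i in seq_along(ts)) {
    emit(sink, ch, "temp_humidity", rep(ts[i], 2), c("temp_c", "rh"), c(temp[i], rh[i]))
  }
}

em_temp_ambient <- function(sink, ch, t_from, t_to, ambient) {
  ts <- seq(t_from, t_to, by = 1800)
  for (t in ts) {
    emit(
      sink, ch, "temp_humidity", rep(t, 2), c("temp_c", "rh"),
      c(ambient + rnorm(1, 0, 0.2), 45 + rnorm(1, 0, 2))
    )
  }
}

# --- lidar walking -----------------------------------------------------------

draw_gait_speed_ms <- function(persona, n) {
  # near-zero rejection floor keeps the sampled mean at the configured value
  v <- rnorm(n, persona$gait_speed_mean_kmh, persona$gait_speed_sd_kmh)
  bad <- v < 0.01
  while (any(bad)) {
    v[bad] <- rnorm(sum(bad), persona$gait_speed_mean_kmh, persona$gait_speed_sd_kmh)
    bad <- v < 0.01
  }
  v / 3.6
}

#' Simulate a lidar walk between two zones
#'
#' Samples a straight-line track between the centroids of two zones at
#' (nominally) 1 Hz, with each step's speed drawn from the persona's gait
#' speed distribution. The arrival step uses fractional time so every
#' recovered inter-sample speed is a draw from the configured distribution.
#'
#' @param zm A [zone_map()].
#' @param from_zone,to_zone Zone ids (1-6).
#' @param persona A [persona_params()].
#' @param t0 Start instant (numeric seconds or POSIXct).
#' @return Tibble with `t` (numeric seconds), `x`, `y`.
#' @export
simulate_walk <- function(zm, from_zone, to_zone, persona, t0) {
  if (inherits(t0, "POSIXct")) t0 <- as.numeric(t0)
  a <- zone_centroid(zm, from_zone)
  b <- zone_centroid(zm, to_zone)
  L <- sqrt(sum((b - a)^2))
  if (L < 1e-9) {
    return(tibble(t = t0, x = a[["x"]], y = a[["y"]]))
  }
  pos <- 0
  t <- t0
  ts <- t0
  ps <- 0
  while (pos < L) {
    v <- draw_gait_speed_ms(persona, 1)
    if (pos + v >= L) {
      t <- t + (L - pos) / v
      pos <- L
    } else {
      t <- t + 1
      pos <- pos + v
    }
    ts <- c(ts, t)
    ps <- c(ps, pos)
  }
  frac <- ps / L
  tr <- tibble(
    t = round(ts, 3),
    x = a[["x"]] + frac * (b[["x"]] - a[["x"]]),
    y = a[["y"]] + frac * (b[["y"]] - a[["y"]])
  )
  # a sub-millisecond arrival step can round onto the previous sample
  tr[c(diff(tr$t) > 0, TRUE), , drop = FALSE]
}

em_walk <- function(sink, household, from_zone, to_zone, persona, t0) {
  tr <- simulate_walk(household$zone_map, from_zone, to_zone, persona, t0)
  for (i in seq_len(nrow(tr))) {
    emit(
      sink, household$lidar_channel, "lidar", rep(tr$t[i], 2),
      c("x", "y"), c(tr$x[i], tr$y[i])
    )
  }
  max(tr$t)
}

# --- one simulated day -------------------------------------------------------

zone_of_name <- function(zm, name) zm$zones$zone_id[match(name, zm$zones$name)]

motion_channel_for_zone <- function(household, zone) {
  r <- household$roster
  r$channel_id[r$sensor_type == "motion" & r$zone_id == zone & r$active][1]
}

#' Simulate one person-day of raw sensor events
#'
#' Uses the RNG state in place; wrap in [withr::with_seed()] (as
#' [generate_cohort()] does) for reproducibility.
#'
#' @param profile List with `person_id`, `group`, and `persona`
#'   (a [persona_params()]).
#' @param date Calendar day, `"YYYY-MM-DD"`.
#' @param household Household configuration, as [reference_household()].
#' @return Tibble of sensor events (`timestamp`, `person_id`, `channel_id`,
#'   `sensor_type`, `field`, `value`), time-sorted.
#' @export
simulate_person_day <- function(profile, date, household = reference_household()) {
  p <- profile$persona
  zm <- household$zone_map
  R <- function(role) role_channel(household, role)
  t0 <- as.numeric(as.POSIXct(paste0(date, " 00:00:00"), tz = TZ))
  day_end <- t0 + 86400 - 5
  sink <- new_event_sink()
  scale <- p$task_duration_scale

  z_liv <- zone_of_name(zm, "living_room")
  z_kit <- zone_of_name(zm, "kitchen")
  z_bed <- zone_of_name(zm, "bedroom")
  z_bath <- zone_of_name(zm, "bathroom")
  z_ent <- zone_of_name(zm, "entrance")
  cur_zone <- z_bed
  last_walk_end <- -Inf

  # walks are serialized: one tracked body, so a walk starting inside the
  # previous walk is pushed just past it (activity times stay as scheduled)
  goto <- function(zone, t) {
    if (zone != cur_zone) {
      t <- max(t, last_walk_end + 2)
      t <- em_walk(sink, household, cur_zone, zone, p, t)
      last_walk_end <<- t
      cur_zone <<- zone
    }
    t
  }
  motion_burst <- function(zone, t_from, t_to, rate_per_h) {
    n <- rpois(1, max(0, (t_to - t_from) / 3600 * rate_per_h))
    if (n > 0) {
      em_motion(sink, motion_channel_for_zone(household, zone), sort(runif(n, t_from, t_to)))
    }
  }

  wake <- t0 + clamp(p$wake_hour + rnorm(1, 0, 0.3), 5.1, 9.5) * 3600
  sleep <- t0 + clamp(p$sleep_hour + rnorm(1, 0, 0.4), 20.5, 23.8) * 3600

  # --- 00:00-05:00 night window: active only through night awakenings -------
  n_night <- rpois(1, p$night_activity_rate * 5)
  night_times <- sort(runif(n_night, t0 + 300, t0 + 5 * 3600 - 1500))
  for (tn in night_times) {
    dest <- sample(c(z_liv, z_bath), 1)
    t_arr <- goto(dest, tn)
    dur <- runif(1, 300, 1200) * scale
    motion_burst(dest, t_arr, t_arr + dur, 20)
    if (dest == z_bath && runif(1) < 0.4) {
      em_vib_use(sink, R("bathroom_faucet"), t_arr + runif(1, 10, dur / 2), runif(1, 20, 90))
    }
    if (dest == z_liv && runif(1) < p$tv_night_prob) {
      ton <- t_arr + runif(1, 10, 60)
      em_plug(sink, R("tv_plug"), ton, min(ton + runif(1, 900, 2700), t0 + 5 * 3600 - 60), 60)
    }
    goto(z_bed, t_arr + dur)
  }
  # early-morning electric-mat segment rides on night wakefulness
  if (runif(1) < p$mat_night_prob * (1 - exp(-p$night_activity_rate)) && n_night > 0) {
    emit(sink, R("mat_plug"), "plug", night_times[1], "power_w", 45)
    emit(sink, R("mat_plug"), "plug", wake + runif(1, 0, 600), "power_w", 0)
  }

  # --- daily sensor baselines (from 05:00 so an eventless night stays silent)
  base_t <- t0 + 5 * 3600 + 2
  for (role in c(
    "pill_organizer", "refrigerator", "rice_cooker", "kitchen_sink_faucet",
    "bathroom_faucet", "showerhead", "hairdryer", "fan", "vacuum_cleaner", "bin"
  )) {
    em_vib_rest(sink, R(role), base_t)
    base_t <- base_t + 0.25
  }
  for (role in c("tv_plug", "mat_plug", "washer_plug", "lamp_plug")) {
    emit(sink, R(role), "plug", base_t, "power_w", 0)
    base_t <- base_t + 0.25
  }
  # daily supervision heartbeat: doors report their closed state, motion
  # sensors report ambient lux; neither adds counts or durations downstream
  act <- household$roster[household$roster$active, ]
  for (ch in act$channel_id[act$sensor_type == "door"]) {
    emit(sink, ch, "door", base_t, "link", 1)
    base_t <- base_t + 0.25
  }
  for (ch in act$channel_id[act$sensor_type == "motion"]) {
    emit(sink, ch, "motion", base_t, "lux", 180 + rnorm(1, 0, 20))
    base_t <- base_t + 0.25
  }
  em_temp_ambient(sink, R("stove_temp"), t0 + 5 * 3600 + 10, day_end, 22)
  em_temp_ambient(sink, R("bathroom_temp"), t0 + 5 * 3600 + 20, day_end, 21.5)

  # --- wake and grooming -----------------------------------------------------
  t_arr <- goto(z_bath, wake)
  em_vib_use(sink, R("bathroom_faucet"), t_arr + runif(1, 30, 120), runif(1, 45, 150) * scale)
  motion_burst(z_bath, t_arr, t_arr + 900 * scale, 25)
  if (runif(1) < p$shower_prob) {
    t_sh <- t_arr + runif(1, 300, 900)
    dur_sh <- runif(1, 420, 900) * scale
    em_vib_use(sink, R("showerhead"), t_sh, dur_sh)
    em_temp_profile(sink, R("bathroom_temp"), t_sh, dur_sh, 21.5, 4)
    if (runif(1) < 0.6) {
      em_vib_use(sink, R("hairdryer"), t_sh + dur_sh + runif(1, 60, 240), runif(1, 90, 240))
    }
  }
  goto(z_liv, t_arr + 1000 * scale)

  # --- meals -----------------------------------------------------------------
  meal_centers <- c(
    breakfast = clamp(rnorm(1, 8, 0.6), 5.3, 9.7),
    lunch = clamp(rnorm(1, 13, 0.5), 12.2, 14.7),
    dinner = clamp(rnorm(1, 18.3, 0.6), 17.2, 19.7)
  )
  coh <- p$appliance_coherence
  for (i in 1:3) {
    t_meal <- t0 + meal_centers[i] * 3600
    if (runif(1) < p$meal_cook_prob[i]) {
      t_arr <- goto(z_kit, t_meal - 120)
      dur_cook <- runif(1, 12, 28) * 60 * scale
      em_temp_profile(sink, R("stove_temp"), t_meal, dur_cook, 22, 6)
      if (runif(1) < coh) {
        em_vib_use(sink, R("refrigerator"), t_meal + runif(1, -180, 480), runif(1, 10, 40))
      }
      if (runif(1) < coh) {
        em_vib_use(sink, R("kitchen_sink_faucet"), t_meal + runif(1, 0, 900), runif(1, 30, 150))
      }
      if (i != 2 && runif(1) < coh * 0.7) {
        em_vib_use(sink, R("rice_cooker"), t_meal + runif(1, -120, 600), runif(1, 15, 45))
      }
      if (runif(1) < 0.25 + 0.5 * coh) {
        td <- t_meal + runif(1, 0, 600)
        em_door(sink, R("cupboard"), td, td + runif(1, 10, 60))
      }
      motion_burst(z_kit, t_meal - 120, t_meal + dur_cook, 30)
      t_after <- t_meal + dur_cook
      if (runif(1) < p$dishes_prob) {
        em_vib_use(
          sink, R("kitchen_sink_faucet"), t_after + runif(1, 300, 1200),
          runif(1, 45, 220) * scale
        )
      }
      goto(z_liv, t_after + 300)
    } else if (runif(1) < 0.45) {
      # heated meal: microwave without the stove
      t_arr <- goto(z_kit, t_meal)
      em_door(sink, R("microwave"), t_arr + 30, t_arr + 30 + runif(1, 40, 120))
      if (runif(1) < 0.35) {
        em_vib_use(sink, R("refrigerator"), t_arr + runif(1, 0, 240), runif(1, 10, 30))
      }
      motion_burst(z_kit, t_arr, t_arr + 600, 25)
      goto(z_liv, t_arr + 700)
    }
  }

  # scattered, task-unrelated kitchen appliance touches (incoherence)
  n_scatter <- rpois(1, (1 - coh) * 4)
  for (ts in runif(n_scatter, wake + 600, sleep - 600)) {
    role <- sample(c("refrigerator", "kitchen_sink_faucet", "rice_cooker", "cupboard"), 1)
    if (role == "cupboard") {
      em_door(sink, R("cupboard"), ts, ts + runif(1, 10, 40))
    } else {
      em_vib_use(sink, R(role), ts, runif(1, 10, 60))
    }
  }

  # --- medications ------------------------------------------------------------
  for (dose_h in c(8, 13.5, 18.5, 21.75)) {
    if (runif(1) < p$med_adherence_prob) {
      td <- t0 + dose_h * 3600 + rnorm(1, 0, p$med_time_jitter_min * 60)
      td <- clamp(td, wake + 60, day_end - 120)
      em_vib_use(sink, R("pill_organizer"), td, runif(1, 20, 60))
    }
  }

  # --- outing -----------------------------------------------------------------
  outing <- NULL
  if (runif(1) < p$outing_prob) {
    leave <- t0 + (sample(c(10.2, 15.2), 1) + rnorm(1, 0, 0.2)) * 3600
    dur_out <- runif(1, 50, 95) * 60
    ret <- leave + dur_out
    outing <- c(leave, ret)
    goto(z_ent, leave - 90)
    em_door(sink, R("entrance_door"), leave - 20, leave)
    forget <- runif(1) < p$forget_appliance_on_prob
    if (forget) {
      app <- sample(c("tv_plug", "mat_plug"), 1)
      em_plug(
        sink, R(app), leave - runif(1, 600, 1800), ret + runif(1, 600, 1800),
        if (app == "tv_plug") 60 else 45
      )
    }
    em_door(sink, R("entrance_door"), ret, ret + 20)
    em_motion(sink, motion_channel_for_zone(household, z_ent), ret + c(35, 70))
    cur_zone <- z_ent
    goto(z_liv, ret + 90)
    if (runif(1) < 0.5) {
      ton <- ret + runif(1, 120, 1500)
      em_plug(sink, R("tv_plug"), ton, ton + runif(1, 1800, 5400), 60)
    }
  }

  # --- chores -----------------------------------------------------------------
  if (runif(1) < p$washer_prob) {
    tw <- t0 + runif(1, 10.5, 12) * 3600
    em_plug(sink, R("washer_plug"), tw, tw + 2400, 500)
  }
  if (runif(1) < p$vacuum_prob) {
    tv <- t0 + runif(1, 9.5, 11.5) * 3600
    em_vib_use(sink, R("vacuum_cleaner"), tv, runif(1, 480, 1200))
  }
  for (tb in runif(sample(1:2, 1), wake + 300, sleep - 300)) {
    em_vib_use(sink, R("bin"), tb, runif(1, 4, 12))
  }
  if (runif(1) < 0.5) {
    em_vib_use(sink, R("fan"), t0 + runif(1, 13, 16) * 3600, runif(1, 600, 1800))
  }

  # --- TV, lamp, mat ----------------------------------------------------------
  if (runif(1) < p$tv_morning_prob) {
    ton <- t0 + runif(1, 7.2, 8.5) * 3600
    em_plug(sink, R("tv_plug"), ton, ton + runif(1, 1800, 4200), 60)
  }
  tv_eve_on <- t0 + clamp(rnorm(1, 19, 0.5), 18.2, 20.5) * 3600
  em_plug(sink, R("tv_plug"), tv_eve_on, min(sleep - 300, day_end), 60)
  em_plug(sink, R("lamp_plug"), t0 + 18.5 * 3600, min(sleep, day_end), 12)
  if (runif(1) < p$mat_night_prob) {
    em_plug(sink, R("mat_plug"), sleep - runif(1, 0, 600), day_end, 45)
  }
  if (runif(1) < p$mat_day_prob) {
    tm <- t0 + runif(1, 12.2, 14.5) * 3600
    em_plug(sink, R("mat_plug"), tm, tm + runif(1, 3600, 7200), 45)
  }

  # --- background occupancy motion and wandering walks ------------------------
  motion_burst(z_bed, t0 + 5 * 3600, wake, 2)
  motion_burst(z_liv, wake + 900, sleep, 16)
  motion_burst(z_bed, sleep, day_end, 2)
  n_wander <- rpois(1, p$wander_walks_per_day)
  for (tw in runif(n_wander, wake + 1200, sleep - 1200)) {
    dest <- sample(setdiff(zm$zones$zone_id, z_liv), 1)
    t_arr <- goto(dest, tw)
    motion_burst(dest, t_arr, t_arr + runif(1, 120, 600), 20)
    goto(z_liv, t_arr + runif(1, 150, 650))
  }

  ev <- collect_events(sink, profile$person_id)
  ev <- ev[as.numeric(ev$timestamp) <= day_end + 960, , drop = FALSE]
  # an empty dwelling is silent: drop presence-bound events during the outing
  if (!is.null(outing)) {
    t_num <- as.numeric(ev$timestamp)
    interior <- ev$sensor_type %in% c("motion", "lidar", "vibration") |
      (ev$sensor_type == "door" & ev$channel_id != role_channel(household, "entrance_door"))
    drop <- interior & t_num > outing[1] & t_num < outing[2]
    ev <- ev[!drop, , drop = FALSE]
  }
  ev
}

# --- cohort ------------------------------------------------------------------

#' Generate a synthetic smart-home cohort
#'
#' Draws per-person cognitive profiles (MMSE/CDR by group) and personas from
#' the group templates, then simulates `days` days of raw sensor events per
#' person. Deterministic for a given `(config, seed)`: every person-day runs
#' under its own derived seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer root seed.
#' @param household Household configuration, as [reference_household()].
#' @return List with `profiles` (tibble: `person_id`, `group`, `mmse`, `cdr`,
#'   list-column `persona`), `events` (named list of per-person event
#'   tibbles), `config`, and `household`.
#' @export
generate_cohort <- function(config, seed, household = reference_household()) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- c(rep("normal", config$n_normal), rep("dementia", config$n_dementia))
  ids <- sprintf("P%02d", seq_along(groups))
  cog <- withr::with_seed(derive_seed(seed, 1), bind_rows(
    assign_cognition("normal", config$n_normal, config$mmse$normal),
    assign_cognition("dementia", config$n_dementia, config$mmse$dementia)
  ))
  personas <- withr::with_seed(derive_seed(seed, 2), lapply(
    seq_along(groups),
    function(i) jitter_persona(config$personas[[groups[i]]])
  ))
  profiles <- tibble(
    person_id = ids, group = groups,
    mmse = cog$mmse, cdr = cog$cdr, persona = personas
  )
  dates <- as.Date(config$start_date) + seq_len(config$days) - 1
  events <- lapply(seq_along(ids), function(i) {
    prof <- list(person_id = ids[i], group = groups[i], persona = personas[[i]])
    days <- lapply(seq_along(dates), function(d) {
      withr::with_seed(
        derive_seed(seed, 100 + i, d),
        simulate_person_day(prof, as.character(dates[d]), household)
      )
    })
    arrange(bind_rows(days), .data$timestamp, .data$channel_id, .data$field)
  })
  names(events) <- ids
  list(profiles = profiles, events = events, config = config, household = household)
}
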