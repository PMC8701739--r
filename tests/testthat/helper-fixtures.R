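# Hand-constructed event fixtures for rule tracing, plus a lazily cached
# small synthetic cohort shared across tests.

t_at <- function(hms, date = "2020-07-06") {
  as.numeric(as.POSIXct(paste(date, hms), tz = "UTC"))
}

mk_events <- function(t, channel_id, sensor_type, field, value,
                      person_id = "T01") {
  tibble::tibble(
    timestamp = as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
    person_id = person_id, channel_id = channel_id,
    sensor_type = sensor_type, field = field, value = value
  )
}

# resting tilt sample(s) (flat pose); vectorized over t
vib_rest <- function(ch, t) {
  dplyr::bind_rows(lapply(t, function(ti) {
    mk_events(rep(ti, 3), ch, "vibration", c("tilt_x", "tilt_y", "tilt_z"), c(0, 0, 1))
  }))
}

# deviate at t, restore at t + dur
vib_use <- function(ch, t, dur, angle_deg = 30) {
  a <- angle_deg * pi / 180
  dplyr::bind_rows(
    mk_events(rep(t, 3), ch, "vibration", c("tilt_x", "tilt_y", "tilt_z"),
      c(sin(a), 0, cos(a))),
    mk_events(rep(t + dur, 3), ch, "vibration", c("tilt_x", "tilt_y", "tilt_z"),
      c(0, 0, 1))
  )
}

plug_step <- function(ch, t, w) mk_events(t, ch, "plug", "power_w", w)

door_evt <- function(ch, t, state) mk_events(t, ch, "door", "state", state)

motion_evt <- function(ch, t, lux = 100) {
  dplyr::bind_rows(lapply(t, function(ti) {
    mk_events(rep(ti, 2), ch, "motion", c("detected", "lux"), c(1, lux))
  }))
}

temp_evt <- function(ch, t, temp, rh = 45) {
  dplyr::bind_rows(lapply(seq_along(t), function(i) {
    mk_events(rep(t[i], 2), ch, "temp_humidity", c("temp_c", "rh"), c(temp[i], rh))
  }))
}

lidar_pts <- function(t, x, y, ch = "lidar1") {
  dplyr::bind_rows(lapply(seq_along(t), function(i) {
    mk_events(rep(t[i], 2), ch, "lidar", c("x", "y"), c(x[i], y[i]))
  }))
}

# simple episode-table builder for the ADL rule functions
ep <- function(channel_id, start, end, kind = "tilt_use", role = NULL) {
  out <- tibble::tibble(
    channel_id = channel_id,
    start = as.POSIXct(start, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(end, origin = "1970-01-01", tz = "UTC"),
    kind = kind
  )
  if (!is.null(role)) out$role <- role
  out
}

# shared small cohort (3 normal + 3 dementia, 4 days), built once per run
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_config(3, 3, days = 4), seed = 101)
    }
    cache
  }
})

small_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- cohort_features(small_cohort())
    cache
  }
})
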