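# Per-sensor conversions, binning arithmetic, lidar kinematics, zone visits.

test_that("malformed log lines are skipped with their line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  good <- door_evt("d1", t_at("08:00:00") + 0:9 * 60, rep(c(1, 0), 5))
  write_event_log(good, path)
  lines <- readLines(path)
  lines[5] <- "not,a,valid,line"
  writeLines(lines, path)
  expect_warning(ev <- read_event_log(path), "line")
  expect_equal(nrow(ev), 9)
  # unknown channels are skipped with a warning when a roster is given
  expect_warning(
    ev2 <- read_event_log(path, roster = "other"),
    "unknown channel"
  ) |> expect_warning("malformed")
  expect_equal(nrow(ev2), 0)
  expect_error(read_event_log(file.path(tempdir(), "nope.csv")), "no such")
})

test_that("vibration episodes follow the deviate/restore rule", {
  ch <- dplyr::bind_rows(
    vib_rest("v4", t_at("07:00:00")),
    vib_use("v4", t_at("08:00:00"), 60)
  )
  ep1 <- vibration_use_episodes(ch)
  expect_equal(nrow(ep1), 1)
  expect_equal(as.numeric(ep1$end - ep1$start, units = "secs"), 60)
  # constant tilt: no episodes
  flat <- dplyr::bind_rows(vib_rest("v4", t_at("07:00:00") + 0:5 * 60))
  expect_equal(nrow(vibration_use_episodes(flat)), 0)
  # deviation with no restore is truncated at the timeout
  a <- 30 * pi / 180
  noret <- dplyr::bind_rows(
    vib_rest("v4", t_at("07:00:00") + c(0, 60)),
    mk_events(rep(t_at("08:00:00"), 3), "v4", "vibration",
      c("tilt_x", "tilt_y", "tilt_z"), c(sin(a), 0, cos(a))
    )
  )
  ep2 <- vibration_use_episodes(noret, timeout_s = 600)
  expect_equal(nrow(ep2), 1)
  expect_equal(as.numeric(ep2$end - ep2$start, units = "secs"), 600)
  # sub-tolerance wobble is not a use
  a2 <- 5 * pi / 180
  wob <- dplyr::bind_rows(
    vib_rest("v4", t_at("07:00:00") + c(0, 60)),
    mk_events(rep(t_at("08:00:00"), 3), "v4", "vibration",
      c("tilt_x", "tilt_y", "tilt_z"), c(sin(a2), 0, cos(a2))
    )
  )
  expect_equal(nrow(vibration_use_episodes(wob, tilt_tol_deg = 10)), 0)
})

test_that("plug on-intervals threshold, close and debounce correctly", {
  ch <- dplyr::bind_rows(
    plug_step("p1", t_at("19:00:00"), 0),
    plug_step("p1", t_at("20:00:00"), 60),
    plug_step("p1", t_at("21:30:00"), 0)
  )
  iv <- plug_on_intervals(ch)
  expect_equal(nrow(iv), 1)
  expect_equal(as.numeric(iv$end - iv$start, units = "mins"), 90)
  # all-zero power: nothing
  expect_equal(nrow(plug_on_intervals(plug_step("p1", t_at("10:00:00") + 0:3, 0))), 0)
  # two on-periods separated by 30 s merge under a 60 s debounce
  ch2 <- dplyr::bind_rows(
    plug_step("p1", t_at("10:00:00"), 60),
    plug_step("p1", t_at("10:05:00"), 0),
    plug_step("p1", t_at("10:05:30"), 60),
    plug_step("p1", t_at("10:10:00"), 0)
  )
  expect_equal(nrow(plug_on_intervals(ch2, debounce_s = 60)), 1)
  expect_equal(nrow(plug_on_intervals(ch2, debounce_s = 10)), 2)
  expect_error(plug_on_intervals(ch, on_threshold_w = -1), class = "adlsense_config_error")
})

test_that("temperature rises are detected against a rolling baseline", {
  flat <- temp_evt("t1", t_at("08:00:00") + 0:30 * 60, rep(22, 31))
  expect_equal(nrow(temp_rise_episodes(flat, delta_c = 2)), 0)
  ramp_once <- c(rep(22, 10), 22 + (1:10) * 0.5, 27 - (1:15) * 0.4)
  e1 <- temp_rise_episodes(temp_evt("t1", t_at("08:00:00") + seq_along(ramp_once) * 60, ramp_once), delta_c = 2)
  expect_equal(nrow(e1), 1)
  two <- c(rep(22, 8), 22 + (1:6), 28 - (1:6), rep(22, 20), 22 + (1:6), 28 - (1:6), rep(22, 8))
  e2 <- temp_rise_episodes(temp_evt("t1", t_at("08:00:00") + seq_along(two) * 60, two), delta_c = 2)
  expect_equal(nrow(e2), 2)
})

test_that("binning splits durations across bins and counts start bins", {
  # a 90-minute interval from 20:15 overlaps two hourly bins 45/45 min
  iv <- ep("p1", t_at("20:15:00"), t_at("21:45:00"), "plug_on")
  b <- bin_counts_durations(iv, "1 hour")
  expect_equal(nrow(b), 2)
  expect_equal(b$duration_s, c(2700, 2700))
  expect_equal(b$count, c(1L, 0L))
  # five door togglings in one day: day-level count 5
  pts <- ep("d1", t_at("08:00:00") + 1:5 * 600, t_at("08:00:00") + 1:5 * 600)
  bd <- bin_counts_durations(pts, "1 day")
  expect_equal(bd$count, 5L)
  expect_equal(bd$duration_s, 0)
  # an episode exactly filling a bin has duration equal to the bin width
  full <- ep("p1", t_at("10:00:00"), t_at("11:00:00"), "plug_on")
  bf <- bin_counts_durations(full, "1 hour")
  expect_equal(bf$duration_s[1], 3600)
  expect_equal(bf$count[1], 1L)
})

test_that("binned durations conserve episode time and refine consistently", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      # non-overlapping episodes, as one physical channel produces
      n <- 30
      bounds <- sort(runif(2 * n, 0, 86400))
      s <- t_at("00:00:00") + bounds[seq(1, 2 * n, 2)]
      e <- t_at("00:00:00") + bounds[seq(2, 2 * n, 2)]
      eps <- ep("x1", s, e, "plug_on")
      day0 <- as.POSIXct(t_at("00:00:00"), origin = "1970-01-01", tz = "UTC")
      day1 <- day0 + 86400
      for (bw in c("10 min", "1 hour", "1 day")) {
        b <- bin_counts_durations(eps, bw, origin = day0, end = day1)
        expect_equal(sum(b$duration_s), sum(e - s), tolerance = 1e-6)
        expect_equal(sum(b$count), n)
        expect_true(all(b$duration_s <= bin_width_seconds(bw) + 1e-9))
      }
      # day counts = sum of hourly counts = sum of 10-minute counts
      c_day <- sum(bin_counts_durations(eps, "1 day", day0, day1)$count)
      c_hr <- sum(bin_counts_durations(eps, "1 hour", day0, day1)$count)
      c_10 <- sum(bin_counts_durations(eps, "10 min", day0, day1)$count)
      expect_equal(c_day, c_hr)
      expect_equal(c_hr, c_10)
    }
  })
})

test_that("lidar kinematics convert, filter and accumulate correctly", {
  # 1 m in 1 s is 3.6 km/h
  tr <- tibble::tibble(
    timestamp = as.POSIXct(t_at("10:00:00") + 0:1, origin = "1970-01-01", tz = "UTC"),
    x = c(0, 1), y = c(0, 0)
  )
  k <- lidar_kinematics(tr, min_speed_kmh = 0)
  expect_equal(k$speed_kmh, 3.6)
  # stationary track yields no gait samples at the 0.6 km/h floor
  st <- tibble::tibble(
    timestamp = as.POSIXct(t_at("10:00:00") + 0:9, origin = "1970-01-01", tz = "UTC"),
    x = rep(1, 10), y = rep(2, 10)
  )
  expect_equal(sum(lidar_kinematics(st, 0.6)$is_gait), 0)
  # 4 x 5 m rectangle walked at 1 m/s covers its 18 m perimeter
  steps <- rbind(
    matrix(c(1, 0), 4, 2, byrow = TRUE), matrix(c(0, 1), 5, 2, byrow = TRUE),
    matrix(c(-1, 0), 4, 2, byrow = TRUE), matrix(c(0, -1), 5, 2, byrow = TRUE)
  )
  pos <- rbind(c(0, 0), cbind(cumsum(steps[, 1]), cumsum(steps[, 2])))
  sq <- tibble::tibble(
    timestamp = as.POSIXct(t_at("10:00:00") + seq_len(nrow(pos)) - 1,
      origin = "1970-01-01", tz = "UTC"
    ),
    x = pos[, 1], y = pos[, 2]
  )
  ks <- lidar_kinematics(sq, 0.6)
  expect_equal(sum(ks$displacement_m), 18)
  # distance is invariant to the gait floor; gait count is non-increasing
  for (ms in c(0, 0.6, 2, 4)) {
    ki <- lidar_kinematics(sq, ms)
    expect_equal(sum(ki$displacement_m), 18)
  }
  counts <- vapply(c(0, 1, 2, 4), function(ms) sum(lidar_kinematics(sq, ms)$is_gait), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # duplicate timestamps are skipped with a warning
  dup <- sq
  dup$timestamp[3] <- dup$timestamp[2]
  expect_warning(lidar_kinematics(dup), "duplicate")
})

test_that("zone visits merge runs and honor the minimum dwell", {
  zm <- default_zone_map()
  # a track entirely inside the living room is one visit
  tr <- tibble::tibble(
    timestamp = as.POSIXct(t_at("10:00:00") + 0:59, origin = "1970-01-01", tz = "UTC"),
    x = runif(60, 2.5, 5.5), y = runif(60, 0.5, 3.5)
  )
  v <- zone_visits(tr, zm)
  expect_equal(nrow(v), 1)
  expect_equal(v$zone_id, 2L)
  # 10 min in the kitchen then 5 min in the living room: two visits
  tr2 <- tibble::tibble(
    timestamp = as.POSIXct(t_at("10:00:00") + 0:899, origin = "1970-01-01", tz = "UTC"),
    x = c(rep(8, 600), rep(4, 300)), y = rep(2, 900)
  )
  v2 <- zone_visits(tr2, zm)
  expect_equal(v2$zone_id, c(3L, 2L))
  expect_equal(as.numeric(v2$end - v2$start, units = "mins"), c(599 / 60, 299 / 60), tolerance = 0.01)
  # a 2 s excursion under a 5 s dwell floor is discarded and the visit merged
  tr3 <- tibble::tibble(
    timestamp = as.POSIXct(t_at("10:00:00") + 0:60, origin = "1970-01-01", tz = "UTC"),
    x = c(rep(4, 30), rep(8, 2), rep(4, 29)), y = rep(2, 61)
  )
  v3 <- zone_visits(tr3, zm, min_dwell_s = 5)
  expect_equal(nrow(v3), 1)
  expect_equal(v3$zone_id, 2L)
  # a point outside every zone is assigned to the nearest zone
  out_pt <- tibble::tibble(
    timestamp = as.POSIXct(t_at("10:00:00") + 0:9, origin = "1970-01-01", tz = "UTC"),
    x = rep(11, 10), y = rep(2, 10)
  )
  expect_message(vo <- zone_visits(out_pt, zm), "outside")
  expect_equal(vo$zone_id, 3L)
})

test_that("zone maps are validated", {
  zm <- default_zone_map()
  bad <- zm$zones
  bad$x1[1] <- 5 # overlaps living room
  expect_error(zone_map(bad), class = "adlsense_config_error")
  expect_error(zone_map(zm$zones[1:5, ]), class = "adlsense_config_error")
  expect_error(
    zone_map(zm$zones, sensor_placements = c(m1 = 9L)),
    class = "adlsense_config_error"
  )
})
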