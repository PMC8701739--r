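# ADL rule traces: cooking vs heating food, medication windows, appliance
# tags, outing/lock detection, chores thresholds, grooming tags, wandering.

test_that("cooking requires two appliances plus the stove", {
  kitchen <- dplyr::bind_rows(
    ep("v2", t_at("08:00:00"), t_at("08:00:30"), role = "refrigerator"),
    ep("v4", t_at("08:03:00"), t_at("08:04:00"), role = "kitchen_sink_faucet")
  )
  stove <- ep("t1", t_at("08:05:00"), t_at("08:20:00"), "temp_rise")
  got <- detect_cooking(kitchen, stove, person_id = "T01")
  expect_equal(nrow(got), 1)
  expect_equal(got$adl_type, "cooking")
  expect_true(grepl("breakfast", got$tags))
  expect_true(grepl("pair_fridge_sink", got$tags))
  expect_true(grepl("pair_fridge_stove", got$tags))
  expect_false(grepl("pair_sink_ricecooker", got$tags))
  expect_equal(as.numeric(got$start), t_at("08:00:00"))
  expect_equal(as.numeric(got$end), t_at("08:20:00"))

  # microwave alone, no stove rise: heating food, not cooking
  mw <- ep("d2", t_at("12:30:00"), t_at("12:32:00"), "door_open", role = "microwave")
  got2 <- detect_cooking(mw, ep(character(), numeric(), numeric(), "temp_rise")[0, ])
  expect_equal(got2$adl_type, "heating_food")

  # stove rise alone fails the two-appliance condition
  got3 <- detect_cooking(kitchen[0, ], stove)
  expect_equal(nrow(got3), 0)

  # one appliance + stove also fails
  got4 <- detect_cooking(kitchen[1, ], stove)
  expect_equal(nrow(got4), 0)

  # cooking count never exceeds stove rises: far-apart clusters
  k2 <- dplyr::bind_rows(kitchen, dplyr::mutate(kitchen,
    start = start + 6 * 3600, end = end + 6 * 3600
  ))
  s2 <- dplyr::bind_rows(stove, dplyr::mutate(stove,
    start = start + 6 * 3600, end = end + 6 * 3600
  ))
  got5 <- detect_cooking(k2, s2)
  expect_lte(sum(got5$adl_type == "cooking"), nrow(s2))
  expect_equal(nrow(got5), 2)
})

test_that("cooking spans over 30 minutes are tagged", {
  kitchen <- dplyr::bind_rows(
    ep("v2", t_at("17:30:00"), t_at("17:31:00"), role = "refrigerator"),
    ep("v3", t_at("17:40:00"), t_at("17:41:00"), role = "rice_cooker")
  )
  stove <- ep("t1", t_at("17:35:00"), t_at("18:10:00"), "temp_rise")
  got <- detect_cooking(kitchen, stove)
  expect_true(grepl("over_30min", got$tags))
  expect_true(grepl("dinner", got$tags))
})

test_that("medication episodes are tagged by dose window", {
  pills <- dplyr::bind_rows(
    ep("v1", t_at("08:00:00"), t_at("08:01:00")),
    ep("v1", t_at("11:00:00"), t_at("11:00:40")),
    ep("v1", t_at("21:30:00"), t_at("21:30:30"))
  )
  got <- detect_medication(pills, "T01")
  expect_equal(nrow(got), 3)
  expect_equal(got$tags, c("morning", "", "bedtime"))
  expect_equal(nrow(detect_medication(pills[0, ])), 0)
})

test_that("appliance-use episodes carry overlap-based window tags", {
  tv_eve <- ep("p1", t_at("20:00:00"), t_at("21:30:00"), "plug_on")
  got <- detect_appliance_use(tv_eve, tv_eve[0, ])
  expect_equal(got$tags, "tv")
  # an interval spanning 03:00-05:00 overlaps the 00-04 night window
  tv_night <- ep("p1", t_at("03:00:00"), t_at("05:00:00"), "plug_on")
  got2 <- detect_appliance_use(tv_night, tv_night[0, ])
  expect_true(grepl("tv_night", got2$tags))
  expect_true(grepl("tv_morning", got2$tags)) # 04-05 also overlaps 04-12
  mat <- ep("p2", t_at("13:00:00"), t_at("15:00:00"), "plug_on")
  got3 <- detect_appliance_use(mat[0, ], mat)
  expect_true(grepl("mat_daytime", got3$tags))
  expect_false(grepl("mat_night", got3$tags))
  expect_equal(nrow(detect_appliance_use(tv_eve[0, ], tv_eve[0, ])), 0)
})

outing_fixture <- function(tv_on_throughout = FALSE) {
  ev <- dplyr::bind_rows(
    motion_evt("m2", t_at("09:00:00") + 0:5 * 300),
    door_evt("d1", t_at("10:00:00"), 1),
    door_evt("d1", t_at("10:00:20"), 0),
    door_evt("d1", t_at("12:00:00"), 1),
    door_evt("d1", t_at("12:00:20"), 0),
    motion_evt("m2", t_at("12:01:00") + 0:5 * 300),
    plug_step("p1", t_at("08:00:00"), if (tv_on_throughout) 60 else 0)
  )
  dplyr::arrange(ev, timestamp)
}

test_that("outings are detected with lock status", {
  hh <- reference_household()
  got <- detect_outings(outing_fixture(FALSE), hh)
  expect_equal(nrow(got), 1)
  expect_equal(as.numeric(got$leave), t_at("10:00:00"))
  expect_equal(as.numeric(got$return), t_at("12:00:00"))
  expect_true(got$lock_ok)
  expect_equal(got$appliances_left_on, "")

  got2 <- detect_outings(outing_fixture(TRUE), hh)
  expect_false(got2$lock_ok)
  expect_equal(got2$appliances_left_on, "p1")

  # motion one minute after the toggle: no outing
  ev3 <- dplyr::bind_rows(
    door_evt("d1", t_at("10:00:00"), 1),
    motion_evt("m2", t_at("10:01:00")),
    door_evt("d1", t_at("12:00:00"), 1),
    motion_evt("m2", t_at("12:01:00"))
  )
  expect_equal(nrow(detect_outings(dplyr::arrange(ev3, timestamp), hh)), 0)
})

test_that("TV within 30 minutes of return is flagged", {
  hh <- reference_household()
  ev <- dplyr::bind_rows(
    outing_fixture(FALSE),
    plug_step("p1", t_at("12:15:00"), 60),
    plug_step("p1", t_at("13:00:00"), 0)
  )
  got <- detect_outings(dplyr::arrange(ev, timestamp), hh)
  expect_true(got$tv_after_return)
  got0 <- detect_outings(outing_fixture(FALSE), hh)
  expect_false(got0$tv_after_return)
})

test_that("chore rules: the 30 s dishes threshold and laundering", {
  sink <- dplyr::bind_rows(
    ep("v4", t_at("09:00:00"), t_at("09:00:45")),
    ep("v4", t_at("10:00:00"), t_at("10:00:20"))
  )
  washer <- ep("p3", t_at("11:00:00"), t_at("11:40:00"), "plug_on")
  got <- detect_chores(sink, washer)
  expect_equal(sum(got$tags == "dishes"), 1)
  expect_equal(sum(got$tags == "laundering"), 1)
  # raising the threshold never increases the dishes count
  withr::with_seed(31, {
    durs <- runif(50, 5, 300)
    eps <- ep("v4", t_at("08:00:00") + cumsum(durs + 60) - durs, t_at("08:00:00") + cumsum(durs + 60))
    counts <- vapply(c(10, 30, 60, 120, 300), function(th) {
      sum(detect_chores(eps, washer[0, ], dishes_min_s = th)$tags == "dishes")
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("grooming tags: shower, over-a-minute basin, nighttime", {
  basin <- dplyr::bind_rows(
    ep("v5", t_at("07:00:00"), t_at("07:01:30")),
    ep("v5", t_at("02:00:00"), t_at("02:00:30"))
  )
  shower <- ep("v6", t_at("07:10:00"), t_at("07:20:00"))
  got <- detect_grooming(basin, shower, person_id = "T01")
  expect_equal(nrow(got), 3)
  expect_true(grepl("over_1min", got$tags[1]))
  expect_true(grepl("nighttime", got$tags[2]))
  expect_false(grepl("over_1min", got$tags[2]))
  expect_true(grepl("shower", got$tags[3]))
})

test_that("wandering metrics count transitions and night events", {
  # an eventless night scores zero night events
  ev_day <- motion_evt("m2", t_at("10:00:00") + 0:9 * 60)
  w <- detect_wandering(
    tibble::tibble(zone_id = integer(), start = ev_day$timestamp[0], end = ev_day$timestamp[0]),
    ev_day
  )
  expect_equal(sum(w$night_event_count), 0)
  # six zone changes within one hour
  vs <- t_at("14:00:00") + 0:6 * 300
  visits <- tibble::tibble(
    zone_id = c(2L, 3L, 2L, 4L, 2L, 5L, 2L),
    start = as.POSIXct(vs, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(vs + 295, origin = "1970-01-01", tz = "UTC")
  )
  w2 <- detect_wandering(visits, ev_day,
    origin = as.POSIXct(t_at("00:00:00"), origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(t_at("00:00:00") + 86400, origin = "1970-01-01", tz = "UTC")
  )
  expect_equal(sum(w2$n_transitions), 6)
  expect_equal(sum(w2$n_living_transitions), 6) # every change touches the living room
  # a single three-hour stay: one visit, 3 h dwell in that zone
  v3 <- tibble::tibble(
    zone_id = 2L,
    start = as.POSIXct(t_at("13:00:00"), origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(t_at("16:00:00"), origin = "1970-01-01", tz = "UTC")
  )
  w3 <- detect_wandering(v3, ev_day,
    origin = as.POSIXct(t_at("00:00:00"), origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(t_at("00:00:00") + 86400, origin = "1970-01-01", tz = "UTC")
  )
  expect_equal(sum(w3$zone_visits_2), 1)
  expect_equal(sum(w3$zone_dwell_2), 3 * 3600)
  # night events land in the night window bins
  ev_night <- motion_evt("m4", t_at("02:00:00") + 0:9 * 60)
  w4 <- detect_wandering(v3[0, ], ev_night)
  expect_equal(sum(w4$night_event_count), 10)
})

test_that("inferred episodes reference channels installed in the household", {
  cf <- small_features()
  hh <- small_cohort()$household
  known <- c(hh$roster$channel_id, hh$lidar_channel)
  for (pp in cf$per_person) {
    chs <- unlist(strsplit(pp$adl$episodes$channels, ";", fixed = TRUE))
    expect_true(all(chs %in% known))
    # cooking count never exceeds stove temperature rises
    stove <- sum(pp$binned$count[pp$binned$channel_id == "t1"])
    expect_lte(sum(pp$adl$episodes$adl_type == "cooking"), stove)
  }
})
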