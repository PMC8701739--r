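# Synthetic smart-home generator: cohort structure, determinism, marginal
# recovery, and the persona-controlled edge cases.

test_that("cohort has the configured composition and valid profiles", {
  co <- generate_cohort(cohort_config(7, 6, days = 1), seed = 3)
  expect_equal(nrow(co$profiles), 13)
  expect_length(co$events, 13)
  expect_equal(sum(co$profiles$group == "normal"), 7)
  expect_true(all(co$profiles$mmse >= 0 & co$profiles$mmse <= 30))
  expect_true(all(co$profiles$cdr[co$profiles$group == "normal"] == 0))
  expect_true(all(co$profiles$cdr[co$profiles$group == "dementia"] %in% c(0.5, 1)))
  # default cognitive profiles hit the reference group means
  expect_equal(mean(co$profiles$mmse[co$profiles$group == "normal"]), 27.5, tolerance = 0.01)
  expect_equal(mean(co$profiles$mmse[co$profiles$group == "dementia"]), 17.6, tolerance = 0.01)
  # every person has events on every active channel over a two-week stay
  co2 <- small_cohort()
  active <- co2$household$roster$channel_id[co2$household$roster$active]
  for (ev in co2$events) {
    expect_true(all(active %in% unique(ev$channel_id)))
    expect_false(is.unsorted(as.numeric(ev$timestamp)))
  }
})

test_that("invalid cohort configuration is rejected", {
  expect_error(cohort_config(0, 6), class = "adlsense_config_error")
  expect_error(cohort_config(7, 6, days = 0), class = "adlsense_config_error")
  expect_error(persona_params(appliance_coherence = 1.2), class = "adlsense_config_error")
  expect_error(persona_params(task_duration_scale = 0.5), class = "adlsense_config_error")
  expect_error(persona_params(gait_speed_mean_kmh = 0), class = "adlsense_config_error")
})

test_that("generation is deterministic given (config, seed)", {
  c1 <- generate_cohort(cohort_config(2, 2, days = 2), seed = 11)
  c2 <- generate_cohort(cohort_config(2, 2, days = 2), seed = 11)
  expect_identical(c1$events, c2$events)
  expect_identical(
    c1$profiles[, c("person_id", "group", "mmse", "cdr")],
    c2$profiles[, c("person_id", "group", "mmse", "cdr")]
  )
  c3 <- generate_cohort(cohort_config(2, 2, days = 2), seed = 12)
  expect_false(identical(c1$events, c3$events))
})

test_that("zero night-activity rate leaves 00:00-05:00 silent", {
  prof <- list(
    person_id = "P01", group = "normal",
    persona = persona_params(night_activity_rate = 0)
  )
  ev <- withr::with_seed(5, simulate_person_day(prof, "2020-07-06"))
  h <- (as.numeric(ev$timestamp) %% 86400) / 3600
  expect_equal(sum(h < 5), 0)
})

test_that("probability-one personas force their behaviors", {
  hh <- reference_household()
  # cooking every meal window: at least 3 stove temperature rises
  prof <- list(
    person_id = "P01", group = "normal",
    persona = persona_params(meal_cook_prob = c(1, 1, 1))
  )
  ev <- withr::with_seed(7, simulate_person_day(prof, "2020-07-06", hh))
  stove <- temp_rise_episodes(ev[ev$channel_id == "t1", ])
  expect_gte(nrow(stove), 3)
  # forgetful persona: every outing leaves an appliance powered
  prof2 <- list(
    person_id = "P02", group = "dementia",
    persona = persona_params(
      forget_appliance_on_prob = 1, outing_prob = 1, night_activity_rate = 0.2
    )
  )
  n_out <- 0
  for (s in 1:6) {
    ev2 <- withr::with_seed(100 + s, simulate_person_day(prof2, "2020-07-06", hh))
    outs <- detect_outings(ev2, hh)
    n_out <- n_out + nrow(outs)
    if (nrow(outs)) expect_true(all(!outs$lock_ok))
  }
  expect_gt(n_out, 0)
  # tidy persona: outings leave nothing on
  prof3 <- list(
    person_id = "P03", group = "normal",
    persona = persona_params(forget_appliance_on_prob = 0, outing_prob = 1)
  )
  for (s in 1:4) {
    ev3 <- withr::with_seed(200 + s, simulate_person_day(prof3, "2020-07-06", hh))
    outs <- detect_outings(ev3, hh)
    if (nrow(outs)) expect_true(all(outs$lock_ok))
  }
})

test_that("lidar walks recover the configured gait-speed distribution", {
  zm <- default_zone_map()
  for (g in c("normal", "dementia")) {
    p <- default_personas()[[g]]
    sp <- c()
    withr::with_seed(9, {
      while (length(sp) < 10000) {
        tr <- simulate_walk(zm, sample(1:6, 1), sample(setdiff(1:6, 1), 1), p, 0)
        if (nrow(tr) > 1) {
          k <- lidar_kinematics(
            tibble::tibble(
              timestamp = as.POSIXct(tr$t, origin = "1970-01-01", tz = "UTC"),
              x = tr$x, y = tr$y
            ),
            min_speed_kmh = 0
          )
          sp <- c(sp, k$speed_kmh)
        }
      }
    })
    se <- sd(sp) / sqrt(length(sp))
    expect_lt(abs(mean(sp) - p$gait_speed_mean_kmh), 3 * se)
    expect_equal(sd(sp), p$gait_speed_sd_kmh, tolerance = 0.05)
  }
})

test_that("default personas produce the expected group contrasts", {
  co <- small_cohort()
  night_rate <- vapply(co$events, function(ev) {
    h <- (as.numeric(ev$timestamp) %% 86400) / 3600
    sum(h < 5) / length(unique(as.Date(ev$timestamp)))
  }, numeric(1))
  g <- co$profiles$group
  expect_gt(mean(night_rate[g == "dementia"]), mean(night_rate[g == "normal"]))
  # appliance coherence: share of stove episodes that become full cooking
  coherence <- vapply(names(co$events), function(pid) {
    adl <- small_features()$per_person[[pid]]$adl
    eps <- channel_episodes(co$events[[pid]])
    stove <- sum(eps$channel_id == "t1" & eps$kind == "temp_rise")
    if (stove == 0) return(NA_real_)
    sum(adl$episodes$adl_type == "cooking") / stove
  }, numeric(1))
  expect_gt(
    mean(coherence[g == "normal"], na.rm = TRUE),
    mean(coherence[g == "dementia"], na.rm = TRUE)
  )
})

test_that("event logs round-trip losslessly and summarise correctly", {
  co <- generate_cohort(cohort_config(1, 1, days = 1), seed = 21)
  ev <- co$events[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_log(ev, path)
  back <- read_event_log(path)
  expect_equal(nrow(back), nrow(ev))
  expect_equal(as.numeric(back$timestamp), as.numeric(ev$timestamp), tolerance = 1e-3)
  expect_identical(back$value, ev$value)
  expect_identical(back$channel_id, ev$channel_id)
  # empty stream: header-only file
  write_event_log(ev[0, ], path)
  expect_length(readLines(path), 1)
  expect_equal(nrow(read_event_log(path)), 0)
  # five door togglings on one day appear as count 5
  d <- dplyr::bind_rows(lapply(1:5, function(i) {
    door_evt("d1", t_at("08:00:00") + i * 600, i %% 2)
  }))
  rep <- summary_report(d)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$d1, 5L)
})
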