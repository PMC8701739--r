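# Rule-based fusion of per-channel use episodes into the seven ADL activity
# types: cooking (and heating food), taking medications, using household
# appliances, unlocking/closing the entrance door (outings), household
# chores, grooming, and indoor wandering.

ADL_TYPES <- c(
  "cooking", "heating_food", "taking_medications", "grooming",
  "using_appliances", "door_outing", "household_chores", "indoor_wandering"
)

MEAL_WINDOWS <- list(breakfast = c(5, 10), lunch = c(12, 15), dinner = c(17, 20))
MED_WINDOWS <- list(morning = c(5, 10), lunch = c(12, 15), evening = c(17, 20), bedtime = c(21, 24))

adl_episode_tbl <- function(person_id = character(), adl_type = character(),
                            start = ts_of(numeric()), end = ts_of(numeric()),
                            channels = character(), tags = character()) {
  tibble(
    person_id = person_id, adl_type = adl_type, start = start, end = end,
    channels = channels, tags = tags
  )
}

tags_by_start <- function(start, windows) {
  h <- hour_of(start)
  names(windows)[vapply(windows, function(w) h >= w[1] & h < w[2], logical(1))]
}

# seconds of overlap of [s, e) with the daily wall-clock window [lo_h, hi_h)
daily_window_overlap <- function(s, e, lo_h, hi_h) {
  s <- as.numeric(s)
  e <- as.numeric(e)
  total <- 0
  for (d in seq(floor_bin(s, 86400), floor_bin(max(e, s), 86400), by = 86400)) {
    total <- total + overlap_s(s, e, d + lo_h * 3600, d + hi_h * 3600)
  }
  total
}

join_tags <- function(tags) paste(tags, collapse = ";")

has_tag <- function(tag_str, tag) {
  vapply(strsplit(tag_str, ";", fixed = TRUE), function(x) tag %in% x, logical(1))
}

#' Detect cooking and food-heating episodes
#'
#' Kitchen-channel use episodes (refrigerator, rice cooker, kitchen sink
#' faucet, microwave door, cupboard) and gas-stove temperature rises are
#' clustered with a rolling window: an event joins the cluster if it starts
#' within `window_min` minutes of the cluster's latest member. A cluster is
#' a cooking episode iff at least two distinct kitchen appliances and a
#' stove temperature rise contribute; a cluster with the microwave but no
#' stove rise is a heating-food episode. Episode span runs from the earliest
#' to the latest contributing event. Tags: mealtime window of the start
#' (breakfast 05-10, lunch 12-15, dinner 17-20), `over_30min`, and
#' appliance-pair tags for refrigerator-sink, sink-rice-cooker,
#' refrigerator-stove and stove-microwave co-use.
#'
#' @param kitchen_eps Episode tibble with a `role` column for the kitchen
#'   channels.
#' @param stove_eps Temperature-rise episode tibble for the stove channel.
#' @param window_min Rolling cluster window in minutes (default 30).
#' @param person_id Person the episodes belong to.
#' @return ADL episode tibble (types `cooking` / `heating_food`).
#' @export
detect_cooking <- function(kitchen_eps, stove_eps, window_min = 30,
                           person_id = "") {
  stove_eps$role <- if (nrow(stove_eps)) "stove" else character(0)
  all_eps <- bind_rows(
    kitchen_eps[, c("channel_id", "start", "end", "role")],
    stove_eps[, c("channel_id", "start", "end", "role")]
  )
  if (!nrow(all_eps)) return(adl_episode_tbl())
  all_eps <- arrange(all_eps, .data$start)
  s <- as.numeric(all_eps$start)
  cl <- integer(nrow(all_eps))
  cl[1] <- 1
  last_start <- s[1]
  for (i in seq_len(nrow(all_eps))[-1]) {
    if (s[i] - last_start <= window_min * 60) {
      cl[i] <- cl[i - 1]
    } else {
      cl[i] <- cl[i - 1] + 1
    }
    last_start <- s[i]
  }
  out <- list()
  for (k in unique(cl)) {
    g <- all_eps[cl == k, , drop = FALSE]
    appl <- setdiff(unique(g$role), "stove")
    has_stove <- "stove" %in% g$role
    span <- c(min(as.numeric(g$start)), max(as.numeric(g$end)))
    type <- if (has_stove && length(appl) >= 2) {
      "cooking"
    } else if (!has_stove && "microwave" %in% appl) {
      "heating_food"
    } else {
      next
    }
    tags <- tags_by_start(span[1], MEAL_WINDOWS)
    if (type == "cooking") {
      if (span[2] - span[1] > 30 * 60) tags <- c(tags, "over_30min")
      pairs <- list(
        pair_fridge_sink = c("refrigerator", "kitchen_sink_faucet"),
        pair_sink_ricecooker = c("kitchen_sink_faucet", "rice_cooker"),
        pair_fridge_stove = c("refrigerator", "stove"),
        pair_stove_microwave = c("stove", "microwave")
      )
      roles_here <- unique(g$role)
      for (pn in names(pairs)) {
        if (all(pairs[[pn]] %in% roles_here)) tags <- c(tags, pn)
      }
    }
    out[[length(out) + 1]] <- adl_episode_tbl(
      person_id, type, ts_of(span[1]), ts_of(span[2]),
      paste(sort(unique(g$channel_id)), collapse = ";"), join_tags(tags)
    )
  }
  if (!length(out)) return(adl_episode_tbl())
  bind_rows(out)
}

#' Detect medication-taking episodes
#'
#' One episode per pill-organizer use, tagged with the dose window its start
#' falls in (morning 05-10, lunch 12-15, evening 17-20, bedtime 21-24); a
#' use outside every window carries no tag.
#'
#' @param pill_eps Use-episode tibble for the pill-organizer channel.
#' @param person_id Person id.
#' @return ADL episode tibble (type `taking_medications`).
#' @export
detect_medication <- function(pill_eps, person_id = "") {
  if (!nrow(pill_eps)) return(adl_episode_tbl())
  adl_episode_tbl(
    person_id, "taking_medications", pill_eps$start, pill_eps$end,
    pill_eps$channel_id,
    vapply(
      as.numeric(pill_eps$start),
      function(s) join_tags(tags_by_start(s, MED_WINDOWS)), ""
    )
  )
}

#' Detect household-appliance use episodes
#'
#' TV and electric-mat plug on-intervals and fan/vacuum vibration uses each
#' become one episode. TV intervals overlapping 04-12 are tagged
#' `tv_morning`, overlapping 00-04 `tv_night`; mat intervals overlapping
#' 12-16 `mat_daytime` and 00-04 `mat_night` (tag-by-overlap).
#'
#' @param tv_iv,mat_iv Plug on-interval tibbles.
#' @param fan_eps,vacuum_eps Vibration use-episode tibbles.
#' @param person_id Person id.
#' @return ADL episode tibble (type `using_appliances`).
#' @export
detect_appliance_use <- function(tv_iv, mat_iv, fan_eps = empty_episodes(),
                                 vacuum_eps = empty_episodes(), person_id = "") {
  one <- function(eps, base, windows) {
    if (!nrow(eps)) return(adl_episode_tbl())
    tags <- vapply(seq_len(nrow(eps)), function(i) {
      tg <- base
      for (wn in names(windows)) {
        w <- windows[[wn]]
        if (daily_window_overlap(eps$start[i], eps$end[i], w[1], w[2]) > 0) {
          tg <- c(tg, wn)
        }
      }
      join_tags(tg)
    }, "")
    adl_episode_tbl(
      person_id, "using_appliances", eps$start, eps$end, eps$channel_id, tags
    )
  }
  bind_rows(
    one(tv_iv, "tv", list(tv_morning = c(4, 12), tv_night = c(0, 4))),
    one(mat_iv, "mat", list(mat_daytime = c(12, 16), mat_night = c(0, 4))),
    one(fan_eps, "fan", list()),
    one(vacuum_eps, "vacuum", list())
  )
}

#' Detect outings from entrance-door, motion and plug streams
#'
#' An outing opens at an entrance-door toggle followed by at least
#' `quiet_gap_min` minutes with no interior motion, and closes at the next
#' door toggle after which motion resumes within `resume_min` minutes.
#' `appliances_left_on` lists plug channels powered throughout the absence
#' (the living-room lamp plug counts as the lights); `lock_ok` is true iff
#' nothing was left on. `tv_after_return` marks the TV turning on within 30
#' minutes of the return.
#'
#' @param events Full event tibble for one person.
#' @param household Household configuration.
#' @param quiet_gap_min,resume_min Rule windows in minutes.
#' @param plug_on_w Plug on threshold in watts.
#' @return Outing tibble: `person_id`, `leave`, `return`,
#'   `appliances_left_on`, `lock_ok`, `tv_after_return`.
#' @export
detect_outings <- function(events, household, quiet_gap_min = 10,
                           resume_min = 5, plug_on_w = 5) {
  empty <- tibble(
    person_id = character(), leave = ts_of(numeric()),
    return = ts_of(numeric()), appliances_left_on = character(),
    lock_ok = logical(), tv_after_return = logical()
  )
  door_ch <- role_channel(household, "entrance_door")
  door_t <- sort(as.numeric(events$timestamp[
    events$channel_id == door_ch & events$field == "state"
  ]))
  if (length(door_t) < 2) return(empty)
  motion_t <- sort(as.numeric(events$timestamp[
    events$sensor_type == "motion" & events$field == "detected"
  ]))
  plug_ev <- events[events$sensor_type == "plug" & events$field == "power_w", , drop = FALSE]
  plug_series <- split(plug_ev, plug_ev$channel_id)
  person_id <- if (nrow(events)) events$person_id[1] else ""
  tv_ch <- role_channel(household, "tv_plug")

  # step-function test: is the plug on over the whole of [a, b]?
  on_throughout <- function(ser, a, b) {
    t <- as.numeric(ser$timestamp)
    v <- ser$value
    o <- order(t)
    t <- t[o]
    v <- v[o]
    prior <- which(t <= a)
    state0 <- if (length(prior)) v[max(prior)] >= plug_on_w else FALSE
    inside <- v[t > a & t <= b] >= plug_on_w
    state0 && all(inside)
  }
  on_sometime <- function(ser, a, b) {
    t <- as.numeric(ser$timestamp)
    v <- ser$value
    o <- order(t)
    t <- t[o]
    v <- v[o]
    prior <- which(t <= a)
    state0 <- if (length(prior)) v[max(prior)] >= plug_on_w else FALSE
    state0 || any(v[t > a & t <= b] >= plug_on_w)
  }

  out <- list()
  cursor <- -Inf
  for (t in door_t) {
    if (t <= cursor) next
    m_next <- motion_t[motion_t > t]
    quiet_until <- if (length(m_next)) m_next[1] else Inf
    if (quiet_until - t < quiet_gap_min * 60) next
    # find the closing toggle: motion resumes shortly after it
    cand <- door_t[door_t > t]
    t2 <- NA_real_
    for (d2 in cand) {
      m_after <- motion_t[motion_t > d2]
      if (length(m_after) && m_after[1] - d2 <= resume_min * 60) {
        t2 <- d2
        break
      }
    }
    if (is.na(t2)) next
    left_on <- names(plug_series)[vapply(
      plug_series, on_throughout, logical(1), a = t + 30, b = t2 - 30
    )]
    tv_after <- if (!is.null(plug_series[[tv_ch]])) {
      on_sometime(plug_series[[tv_ch]], t2, t2 + 30 * 60)
    } else {
      FALSE
    }
    out[[length(out) + 1]] <- tibble(
      person_id = person_id, leave = ts_of(t), return = ts_of(t2),
      appliances_left_on = paste(sort(left_on), collapse = ";"),
      lock_ok = !length(left_on), tv_after_return = tv_after
    )
    cursor <- t2
  }
  if (!length(out)) return(empty)
  bind_rows(out)
}

#' Detect household-chore episodes
#'
#' Washing dishes: kitchen-sink-faucet uses lasting at least `dishes_min_s`
#' seconds. Laundering: washing-machine plug on-intervals.
#'
#' @param sink_eps Sink-faucet use episodes.
#' @param washer_iv Washer plug on-intervals.
#' @param dishes_min_s Dishes duration threshold (default 30 s).
#' @param person_id Person id.
#' @return ADL episode tibble (type `household_chores`).
#' @export
detect_chores <- function(sink_eps, washer_iv, dishes_min_s = 30, person_id = "") {
  dishes <- sink_eps[
    as.numeric(sink_eps$end) - as.numeric(sink_eps$start) >= dishes_min_s, ,
    drop = FALSE
  ]
  bind_rows(
    if (nrow(dishes)) {
      adl_episode_tbl(
        person_id, "household_chores", dishes$start, dishes$end,
        dishes$channel_id, "dishes"
      )
    } else {
      adl_episode_tbl()
    },
    if (nrow(washer_iv)) {
      adl_episode_tbl(
        person_id, "household_chores", washer_iv$start, washer_iv$end,
        washer_iv$channel_id, "laundering"
      )
    } else {
      adl_episode_tbl()
    }
  )
}

#' Detect grooming episodes
#'
#' One episode per bathroom-basin, showerhead or hairdryer use. Tags:
#' `shower` / `basin` / `hairdryer` by source, `nighttime` when the use
#' starts in 00-04, and `over_1min` for non-shower basin uses of a minute or
#' longer.
#'
#' @param basin_eps,shower_eps,dryer_eps Use-episode tibbles.
#' @param person_id Person id.
#' @return ADL episode tibble (type `grooming`).
#' @export
detect_grooming <- function(basin_eps, shower_eps = empty_episodes(),
                            dryer_eps = empty_episodes(), person_id = "") {
  one <- function(eps, src) {
    if (!nrow(eps)) return(adl_episode_tbl())
    tags <- vapply(seq_len(nrow(eps)), function(i) {
      tg <- src
      h <- hour_of(eps$start[i])
      if (h >= 0 && h < 4) tg <- c(tg, "nighttime")
      dur <- as.numeric(eps$end[i]) - as.numeric(eps$start[i])
      if (src == "basin" && dur >= 60) tg <- c(tg, "over_1min")
      join_tags(tg)
    }, "")
    adl_episode_tbl(person_id, "grooming", eps$start, eps$end, eps$channel_id, tags)
  }
  bind_rows(
    one(basin_eps, "basin"), one(shower_eps, "shower"), one(dryer_eps, "hairdryer")
  )
}

#' Per-bin indoor-wandering metrics
#'
#' Summarises zone visits and nighttime activity per time bin: visits and
#' dwell seconds per zone, zone-transition counts (total and those touching
#' the living room), and the all-channel event count inside the late-night
#' window (00:00-05:00), together with the night-active motion time.
#'
#' @param visits Zone-visit tibble from [zone_visits()].
#' @param events Full event tibble (for the night event count).
#' @param bin_width Bin width (default 1 hour).
#' @param night Night window in hours (default `c(0, 5)`).
#' @param origin,end Optional grid bounds.
#' @return Per-bin tibble of wandering metrics.
#' @export
detect_wandering <- function(visits, events, bin_width = "1 hour",
                             night = c(0, 5), origin = NULL, end = NULL) {
  w <- bin_width_seconds(bin_width)
  if (!nrow(events) && (is.null(origin) || is.null(end))) {
    stop_config("empty events: supply explicit grid bounds")
  }
  span <- if (nrow(events)) range(as.numeric(events$timestamp)) else c(NA, NA)
  g0 <- if (is.null(origin)) floor_bin(span[1], w) else floor_bin(as.numeric(origin), w)
  g1 <- if (is.null(end)) floor_bin(span[2], w) + w else floor_bin(as.numeric(end) - 1e-3, w) + w
  grid <- seq(g0, g1 - w, by = w)
  out <- tibble(
    bin_start = grid, n_transitions = 0L, n_living_transitions = 0L,
    night_event_count = 0L, night_active_s = 0
  )
  for (z in 1:6) {
    out[[paste0("zone_visits_", z)]] <- 0L
    out[[paste0("zone_dwell_", z)]] <- 0
  }
  if (nrow(visits)) {
    vs <- as.numeric(visits$start)
    ve <- as.numeric(visits$end)
    # visit start bin gets the visit count; dwell spreads over bins
    for (i in seq_len(nrow(visits))) {
      b <- floor_bin(vs[i], w)
      j <- match(b, grid)
      if (!is.na(j)) {
        col <- paste0("zone_visits_", visits$zone_id[i])
        out[[col]][j] <- out[[col]][j] + 1L
      }
      bins <- seq(floor_bin(vs[i], w), floor_bin(max(ve[i] - 1e-3, vs[i]), w), by = w)
      dur <- overlap_s(vs[i], ve[i], bins, bins + w)
      jj <- match(bins, grid)
      ok <- !is.na(jj)
      col <- paste0("zone_dwell_", visits$zone_id[i])
      out[[col]][jj[ok]] <- out[[col]][jj[ok]] + dur[ok]
    }
    if (nrow(visits) > 1) {
      living <- zone_of_name(default_zone_map(), "living_room")
      for (i in 2:nrow(visits)) {
        j <- match(floor_bin(vs[i], w), grid)
        if (is.na(j)) next
        out$n_transitions[j] <- out$n_transitions[j] + 1L
        if (visits$zone_id[i] == living || visits$zone_id[i - 1] == living) {
          out$n_living_transitions[j] <- out$n_living_transitions[j] + 1L
        }
      }
    }
  }
  if (nrow(events)) {
    inst <- distinct(events, .data$timestamp, .data$channel_id)
    tt <- as.numeric(inst$timestamp)
    night_i <- hour_of(tt) >= night[1] & hour_of(tt) < night[2]
    if (any(night_i)) {
      tabs <- table(floor_bin(tt[night_i], w))
      jj <- match(as.numeric(names(tabs)), grid)
      ok <- !is.na(jj)
      out$night_event_count[jj[ok]] <- as.integer(tabs[ok])
    }
    mo <- events[events$sensor_type == "motion" & events$field == "detected", , drop = FALSE]
    if (nrow(mo)) {
      bouts <- bind_rows(lapply(split(mo, mo$channel_id), motion_active_bouts))
      if (nrow(bouts)) {
        bs <- as.numeric(bouts$start)
        be <- as.numeric(bouts$end)
        for (i in seq_along(bs)) {
          bins <- seq(floor_bin(bs[i], w), floor_bin(max(be[i] - 1e-3, bs[i]), w), by = w)
          ov <- overlap_s(bs[i], be[i], bins, bins + w)
          # clip each bin's credit to its night-window overlap
          nv <- vapply(bins, function(b) {
            daily_window_overlap(max(bs[i], b), min(be[i], b + w), night[1], night[2])
          }, numeric(1))
          jj <- match(bins, grid)
          ok <- !is.na(jj)
          out$night_active_s[jj[ok]] <- out$night_active_s[jj[ok]] + nv[ok]
        }
      }
    }
  }
  out$bin_start <- ts_of(out$bin_start)
  out
}

#' Run the full ADL inference for one person
#'
#' Converts the raw event stream into channel episodes, then applies every
#' ADL rule, returning the episodes, the outing records and the per-bin
#' wandering metrics.
#'
#' @param events Event tibble for one person.
#' @param household Household configuration.
#' @param thresholds Named list as [default_thresholds()].
#' @param bin_width Bin width for the wandering metrics.
#' @param origin,end Optional grid bounds.
#' @param episodes Optional precomputed [channel_episodes()] output.
#' @return List: `episodes`, `outings`, `wandering`.
#' @export
infer_adl <- function(events, household = reference_household(),
                      thresholds = default_thresholds(),
                      bin_width = "1 hour", origin = NULL, end = NULL,
                      episodes = NULL) {
  th <- modifyList(default_thresholds(), thresholds)
  person_id <- if (nrow(events)) events$person_id[1] else ""
  eps <- episodes %||% channel_episodes(events, th)
  role_of <- setNames(household$roster$role, household$roster$channel_id)
  eps$role <- unname(role_of[eps$channel_id])

  by_role <- function(role, kind = NULL) {
    r <- eps[!is.na(eps$role) & eps$role == role, , drop = FALSE]
    if (!is.null(kind)) r <- r[r$kind == kind, , drop = FALSE]
    r
  }
  kitchen <- eps[!is.na(eps$role) & eps$role %in% kitchen_roles(), , drop = FALSE]
  stove <- by_role("stove_temp", "temp_rise")

  episodes <- bind_rows(
    detect_cooking(kitchen, stove, th$cooking_window_min, person_id),
    detect_medication(by_role("pill_organizer"), person_id),
    detect_appliance_use(
      by_role("tv_plug"), by_role("mat_plug"),
      by_role("fan"), by_role("vacuum_cleaner"), person_id
    ),
    detect_chores(
      by_role("kitchen_sink_faucet"), by_role("washer_plug"),
      th$dishes_min_s, person_id
    ),
    detect_grooming(
      by_role("bathroom_faucet"), by_role("showerhead"),
      by_role("hairdryer"), person_id
    )
  )
  outings <- detect_outings(
    events, household, th$outing_quiet_gap_min, th$outing_resume_min, th$plug_on_w
  )
  if (nrow(outings)) {
    episodes <- bind_rows(episodes, adl_episode_tbl(
      person_id, "door_outing", outings$leave, outings$return,
      role_channel(household, "entrance_door"),
      vapply(seq_len(nrow(outings)), function(i) {
        join_tags(c(
          "outing",
          if (!outings$lock_ok[i]) "no_lock",
          if (outings$tv_after_return[i]) "tv_after_return"
        ))
      }, "")
    ))
  }
  track <- lidar_track(events, household$lidar_channel)
  visits <- zone_visits(track, household$zone_map, th$zone_min_dwell_s)
  wandering <- detect_wandering(visits, events, bin_width,
    origin = origin, end = end
  )
  list(
    episodes = arrange(episodes, .data$start),
    outings = outings, wandering = wandering
  )
}
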