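# The person-hour feature table: one count and one duration feature per
# sensor channel (65 + 65 on the reference roster), two lidar kinematic
# features, and the ADL feature set (31 duration + 32 count = 63), for a
# total of 195 columns on the reference household.

# the ADL items; each has a count and a duration feature, except the
# count-only room-to-living-room transition tally that makes ADL counts 32
ADL_ITEMS <- c(
  "cooking", "cooking_breakfast", "cooking_lunch", "cooking_dinner",
  "cooking_over_30min", "cooking_stove_microwave", "cooking_fridge_sink",
  "cooking_fridge_stove", "cooking_sink_ricecooker", "heating_food",
  "med_morning", "med_lunch", "med_evening", "med_bedtime",
  "grooming_night", "grooming_shower", "grooming_faucet_over_1min",
  "grooming_faucet_total",
  "tv_total", "tv_morning", "tv_night", "tv_after_outing",
  "mat_total", "mat_daytime", "mat_night",
  "laundering", "washing_dishes",
  "outing", "outing_no_lock",
  "room_movement", "night_wandering"
)
ADL_COUNT_ONLY <- "room_transitions"

#' Feature schema for a household configuration
#'
#' One count and one duration feature per roster channel, two lidar features
#' (movement distance, gait speed), and the ADL feature list. Names are
#' deterministic and sorted within each family. On the reference household
#' this yields 132 IoT features (65 + 65 + 2) and 63 ADL features
#' (31 duration + 32 count), 195 in total.
#'
#' @param household Household configuration as [reference_household()], or
#'   `NULL` for an IoT-only schema over `channels`.
#' @param channels Optional explicit channel id vector (overrides the
#'   roster).
#' @param include_lidar,include_adl Switch the lidar / ADL families on or
#'   off.
#' @return A `feature_schema` list with name vectors per family and `all`.
#' @export
feature_schema <- function(household = reference_household(), channels = NULL,
                           include_lidar = TRUE, include_adl = TRUE) {
  chs <- channels %||% household$roster$channel_id
  if (anyDuplicated(chs)) stop_config("duplicate channel ids in roster")
  chs <- sort(chs)
  iot_count <- paste0("iot_count_", chs)
  iot_duration <- paste0("iot_duration_", chs)
  lidar <- if (include_lidar) c("lidar_movement_distance", "lidar_gait_speed") else character()
  adl_duration <- if (include_adl) paste0("adl_duration_", ADL_ITEMS) else character()
  adl_count <- if (include_adl) paste0("adl_count_", sort(c(ADL_ITEMS, ADL_COUNT_ONLY))) else character()
  structure(
    list(
      iot_count = iot_count, iot_duration = iot_duration, lidar = lidar,
      adl_count = adl_count, adl_duration = adl_duration,
      iot = c(iot_count, iot_duration, lidar),
      adl = c(adl_count, adl_duration),
      all = c(iot_count, iot_duration, lidar, adl_count, adl_duration)
    ),
    class = "feature_schema"
  )
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(
    "feature_schema:", length(x$all), "features (IoT", length(x$iot),
    "= count", length(x$iot_count), "+ duration", length(x$iot_duration),
    "+ lidar", length(x$lidar), "; ADL", length(x$adl),
    "= count", length(x$adl_count), "+ duration", length(x$adl_duration), ")\n"
  )
  invisible(x)
}

# map an ADL episode table to item labels; returns tibble(item, start, end)
adl_item_instances <- function(episodes) {
  if (!nrow(episodes)) {
    return(tibble(item = character(), start = ts_of(numeric()), end = ts_of(numeric())))
  }
  rows <- list()
  add <- function(sel, item) {
    if (any(sel)) {
      rows[[length(rows) + 1]] <<- tibble(
        item = item, start = episodes$start[sel], end = episodes$end[sel]
      )
    }
  }
  ty <- episodes$adl_type
  tg <- episodes$tags
  add(ty == "cooking", "cooking")
  add(ty == "cooking" & has_tag(tg, "breakfast"), "cooking_breakfast")
  add(ty == "cooking" & has_tag(tg, "lunch"), "cooking_lunch")
  add(ty == "cooking" & has_tag(tg, "dinner"), "cooking_dinner")
  add(ty == "cooking" & has_tag(tg, "over_30min"), "cooking_over_30min")
  add(ty == "cooking" & has_tag(tg, "pair_stove_microwave"), "cooking_stove_microwave")
  add(ty == "cooking" & has_tag(tg, "pair_fridge_sink"), "cooking_fridge_sink")
  add(ty == "cooking" & has_tag(tg, "pair_fridge_stove"), "cooking_fridge_stove")
  add(ty == "cooking" & has_tag(tg, "pair_sink_ricecooker"), "cooking_sink_ricecooker")
  add(ty == "heating_food", "heating_food")
  add(ty == "taking_medications" & has_tag(tg, "morning"), "med_morning")
  add(ty == "taking_medications" & has_tag(tg, "lunch"), "med_lunch")
  add(ty == "taking_medications" & has_tag(tg, "evening"), "med_evening")
  add(ty == "taking_medications" & has_tag(tg, "bedtime"), "med_bedtime")
  add(ty == "grooming" & has_tag(tg, "nighttime"), "grooming_night")
  add(ty == "grooming" & has_tag(tg, "shower"), "grooming_shower")
  add(ty == "grooming" & has_tag(tg, "over_1min"), "grooming_faucet_over_1min")
  add(ty == "grooming" & (has_tag(tg, "basin") | has_tag(tg, "shower") |
    has_tag(tg, "hairdryer")), "grooming_faucet_total")
  add(ty == "using_appliances" & has_tag(tg, "tv"), "tv_total")
  add(ty == "using_appliances" & has_tag(tg, "tv_morning"), "tv_morning")
  add(ty == "using_appliances" & has_tag(tg, "tv_night"), "tv_night")
  add(ty == "household_chores" & has_tag(tg, "laundering"), "laundering")
  add(ty == "household_chores" & has_tag(tg, "dishes"), "washing_dishes")
  add(ty == "using_appliances" & has_tag(tg, "mat"), "mat_total")
  add(ty == "using_appliances" & has_tag(tg, "mat_daytime"), "mat_daytime")
  add(ty == "using_appliances" & has_tag(tg, "mat_night"), "mat_night")
  add(ty == "door_outing", "outing")
  add(ty == "door_outing" & has_tag(tg, "no_lock"), "outing_no_lock")
  bind_rows(rows)
}

#' Build the person-hour feature table for one person
#'
#' IoT count/duration features come straight from the binned series; lidar
#' features from the binned kinematics; ADL features aggregate the inferred
#' episodes onto the same grid (counts at the episode's start bin, durations
#' as per-bin overlap, capped at the bin width). Window-restricted ADL
#' features (nighttime TV or mat, mealtime cooking, dose windows, late-night
#' wandering) follow the tags assigned by the ADL rules. Hours with no data
#' are zero-filled; labels are *not* joined here (see [join_labels()]).
#'
#' @param binned Output of [binned_series()] (1-hour bins).
#' @param adl Output of [infer_adl()] for the same person.
#' @param lidar_bins Output of `bin_lidar()` on the person's kinematics.
#' @param schema A [feature_schema()].
#' @param origin,end Grid bounds (instants); default to the binned span.
#' @return Wide tibble: `person_id`, `bin_start`, then one column per schema
#'   feature.
#' @export
build_features <- function(binned, adl, lidar_bins, schema,
                           origin = NULL, end = NULL) {
  w <- 3600
  known <- sub("^iot_count_", "", schema$iot_count)
  extra <- setdiff(unique(binned$channel_id), known)
  if (length(extra)) {
    stop_config(paste0("channel(s) not in schema roster: ", paste(extra, collapse = ", ")))
  }
  if (!nrow(binned) && (is.null(origin) || is.null(end))) {
    stop_config("empty binned series: supply explicit grid bounds")
  }
  span <- if (nrow(binned)) range(as.numeric(binned$bin_start)) else c(NA, NA)
  g0 <- if (is.null(origin)) floor_bin(span[1], w) else floor_bin(as.numeric(origin), w)
  g1 <- if (is.null(end)) floor_bin(span[2], w) + w else floor_bin(as.numeric(end) - 1e-3, w) + w
  grid <- seq(g0, g1 - w, by = w)
  person_id <- if (nrow(binned)) binned$person_id[1] else ""
  out <- matrix(0, nrow = length(grid), ncol = length(schema$all),
    dimnames = list(NULL, schema$all)
  )
  # IoT block
  bj <- match(floor_bin(as.numeric(binned$bin_start), w), grid)
  ok <- !is.na(bj)
  cidx <- match(paste0("iot_count_", binned$channel_id), colnames(out))
  didx <- match(paste0("iot_duration_", binned$channel_id), colnames(out))
  for (i in which(ok)) {
    out[bj[i], cidx[i]] <- out[bj[i], cidx[i]] + binned$count[i]
    out[bj[i], didx[i]] <- min(w, out[bj[i], didx[i]] + binned$duration_s[i])
  }
  # lidar block
  if (length(schema$lidar) && nrow(lidar_bins)) {
    lj <- match(floor_bin(as.numeric(lidar_bins$bin_start), w), grid)
    ok <- !is.na(lj)
    out[lj[ok], "lidar_movement_distance"] <- lidar_bins$movement_distance_m[ok]
    out[lj[ok], "lidar_gait_speed"] <- lidar_bins$gait_speed_kmh[ok]
  }
  # ADL block
  if (length(schema$adl)) {
    inst <- adl_item_instances(adl$episodes)
    if (nrow(inst)) {
      s <- as.numeric(inst$start)
      e <- pmax(as.numeric(inst$end), s)
      for (i in seq_len(nrow(inst))) {
        ccol <- paste0("adl_count_", inst$item[i])
        dcol <- paste0("adl_duration_", inst$item[i])
        j <- match(floor_bin(s[i], w), grid)
        if (!is.na(j) && ccol %in% colnames(out)) out[j, ccol] <- out[j, ccol] + 1
        bins <- seq(floor_bin(s[i], w), floor_bin(max(e[i] - 1e-3, s[i]), w), by = w)
        ov <- overlap_s(s[i], e[i], bins, bins + w)
        jj <- match(bins, grid)
        keep <- !is.na(jj)
        if (dcol %in% colnames(out)) {
          out[jj[keep], dcol] <- pmin(w, out[jj[keep], dcol] + ov[keep])
        }
      }
    }
    # tv_after_outing: TV sessions tagged at the outing return
    if (nrow(adl$outings)) {
      ret <- as.numeric(adl$outings$return[adl$outings$tv_after_return])
      if (length(ret)) {
        jj <- match(floor_bin(ret, w), grid)
        for (j in jj[!is.na(jj)]) {
          out[j, "adl_count_tv_after_outing"] <- out[j, "adl_count_tv_after_outing"] + 1
          out[j, "adl_duration_tv_after_outing"] <-
            min(w, out[j, "adl_duration_tv_after_outing"] + 30 * 60)
        }
      }
    }
    # wandering block from the per-bin metrics
    wd <- adl$wandering
    if (nrow(wd)) {
      jj <- match(floor_bin(as.numeric(wd$bin_start), w), grid)
      ok <- !is.na(jj)
      dwell_rooms <- rowSums(as.matrix(
        wd[, paste0("zone_dwell_", setdiff(1:6, zone_of_name(default_zone_map(), "living_room")))]
      ))
      visit_rooms <- rowSums(as.matrix(
        wd[, paste0("zone_visits_", setdiff(1:6, zone_of_name(default_zone_map(), "living_room")))]
      ))
      out[jj[ok], "adl_count_room_movement"] <- visit_rooms[ok]
      out[jj[ok], "adl_duration_room_movement"] <- pmin(w, dwell_rooms[ok])
      out[jj[ok], "adl_count_room_transitions"] <- wd$n_transitions[ok]
      out[jj[ok], "adl_count_night_wandering"] <- wd$night_event_count[ok]
      out[jj[ok], "adl_duration_night_wandering"] <- pmin(w, wd$night_active_s[ok])
    }
  }
  dplyr::bind_cols(
    tibble(person_id = person_id, bin_start = ts_of(grid)),
    as_tibble(out)
  )
}

#' Join group labels onto a feature table
#'
#' Labels come only from the cohort profile table, never from the features
#' themselves.
#'
#' @param features Feature tibble with a `person_id` column.
#' @param profiles Profile tibble (`person_id`, `group`).
#' @return `features` with a `label` factor column (`normal` / `dementia`).
#' @export
join_labels <- function(features, profiles) {
  out <- left_join(features, profiles[, c("person_id", "group")], by = "person_id")
  out$label <- factor(out$group, levels = c("normal", "dementia"))
  out$group <- NULL
  out
}

#' Full preprocessing + inference + featurization for one person
#'
#' @param events Event tibble for one person.
#' @param household Household configuration.
#' @param thresholds Named list as [default_thresholds()].
#' @param schema A [feature_schema()].
#' @param origin,end Grid bounds.
#' @return List: `features`, `binned`, `adl`.
#' @export
process_person <- function(events, household = reference_household(),
                           thresholds = default_thresholds(),
                           schema = feature_schema(household),
                           origin = NULL, end = NULL) {
  eps <- channel_episodes(events, thresholds)
  binned <- binned_series(events, "1 hour", thresholds, origin, end, episodes = eps)
  adl <- infer_adl(events, household, thresholds, "1 hour", origin, end, episodes = eps)
  kin <- lidar_kinematics(
    lidar_track(events, household$lidar_channel),
    thresholds$gait_min_speed_kmh %||% 0.6
  )
  lb <- bin_lidar(kin, "1 hour")
  feats <- build_features(binned, adl, lb, schema, origin, end)
  list(features = feats, binned = binned, adl = adl, kinematics = kin)
}

#' Feature table for a whole simulated cohort
#'
#' Runs [process_person()] for every cohort member on a common hourly grid
#' spanning the configured observation days, and joins group labels.
#'
#' @param cohort Output of [generate_cohort()].
#' @param thresholds Named list as [default_thresholds()].
#' @return List: `features` (labelled person-hour tibble), `schema`,
#'   `per_person` (list of [process_person()] outputs).
#' @export
cohort_features <- function(cohort, thresholds = default_thresholds()) {
  schema <- feature_schema(cohort$household)
  origin <- as.POSIXct(paste0(cohort$config$start_date, " 00:00:00"), tz = TZ)
  end <- origin + cohort$config$days * 86400
  per_person <- lapply(cohort$events, function(ev) {
    process_person(ev, cohort$household, thresholds, schema, origin, end)
  })
  feats <- bind_rows(lapply(per_person, `[[`, "features"))
  list(
    features = join_labels(feats, cohort$profiles),
    schema = schema, per_person = per_person
  )
}
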