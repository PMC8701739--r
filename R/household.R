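# The reference household: the packaged channel roster and the role map the
# ADL rules are wired to. The roster has 65 count/duration channels (8 door,
# 12 motion, 10 smart plug, 5 temperature-humidity, 30 vibration) plus one
# lidar tracker, so the per-channel feature families number 65 each and the
# lidar contributes its two kinematic features. The exact channel composition
# of an instrumented flat is not standardized; this roster is the package's
# documented stand-in, and any household configuration with the same column
# contract can be substituted.

#' Reference household configuration
#'
#' Returns the packaged household: a 65-channel sensor roster (`channel_id`,
#' `sensor_type`, `zone_id`, `role`, `active`), the lidar channel id, the
#' six-zone floor plan, and the role map used by the ADL inference rules.
#' `active` marks channels the synthetic cohort generator actually drives;
#' the remaining channels exist in the roster (and hence in the feature
#' schema) but stay silent, as sparsely used fixtures do in a real dwelling.
#'
#' @return A list with elements `roster` (tibble), `lidar_channel`,
#'   `zone_map`, and `roles` (named list `role -> channel_id`).
#' @export
reference_household <- function() {
  roster <- dplyr::bind_rows(
    tibble(
      channel_id = paste0("d", 1:8), sensor_type = "door",
      zone_id = c(1L, 3L, 3L, 5L, 4L, 2L, 4L, 6L),
      role = c(
        "entrance_door", "microwave", "cupboard", "bathroom_door",
        "bedroom_door", "balcony_door", "wardrobe", "storage_door"
      )
    ),
    tibble(
      channel_id = paste0("m", 1:12), sensor_type = "motion",
      zone_id = c(1:6, 1:6),
      role = c(
        "motion_entrance", "motion_living", "motion_kitchen",
        "motion_bedroom", "motion_bathroom", "motion_storage",
        paste0("motion_aux", 1:6)
      )
    ),
    tibble(
      channel_id = paste0("p", 1:10), sensor_type = "plug",
      zone_id = c(2L, 4L, 6L, 2L, 3L, 3L, 3L, 4L, 2L, 2L),
      role = c(
        "tv_plug", "mat_plug", "washer_plug", "lamp_plug",
        "microwave_plug", "rice_cooker_plug", "kettle_plug",
        "charger_plug", "heater_plug", "air_purifier_plug"
      )
    ),
    tibble(
      channel_id = paste0("t", 1:5), sensor_type = "temp_humidity",
      zone_id = c(3L, 5L, 2L, 4L, 3L),
      role = c(
        "stove_temp", "bathroom_temp", "living_temp", "bedroom_temp",
        "kitchen_temp"
      )
    ),
    tibble(
      channel_id = paste0("v", 1:30), sensor_type = "vibration",
      zone_id = c(
        4L, 3L, 3L, 3L, 5L, 5L, 5L, 2L, 6L, 3L,
        rep(c(2L, 3L, 4L, 5L, 6L), 4)
      ),
      role = c(
        "pill_organizer", "refrigerator", "rice_cooker",
        "kitchen_sink_faucet", "bathroom_faucet", "showerhead",
        "hairdryer", "fan", "vacuum_cleaner", "bin",
        paste0("fixture", 1:20)
      )
    )
  )
  active_roles <- c(
    "entrance_door", "microwave", "cupboard",
    "motion_entrance", "motion_living", "motion_kitchen", "motion_bedroom",
    "motion_bathroom", "motion_storage",
    "tv_plug", "mat_plug", "washer_plug", "lamp_plug",
    "stove_temp", "bathroom_temp",
    "pill_organizer", "refrigerator", "rice_cooker", "kitchen_sink_faucet",
    "bathroom_faucet", "showerhead", "hairdryer", "fan", "vacuum_cleaner",
    "bin"
  )
  roster$active <- roster$role %in% active_roles
  roles <- as.list(setNames(roster$channel_id, roster$role))
  list(
    roster = roster,
    lidar_channel = "lidar1",
    zone_map = default_zone_map(),
    roles = roles
  )
}

# channel_id for a role (errors on unknown role)
role_channel <- function(household, role) {
  ch <- household$roles[[role]]
  if (is.null(ch)) stop_config(paste0("unknown household role: ", role))
  ch
}

# roles treated as kitchen appliances for the cooking rule (stove excluded;
# the stove participates through its temperature-rise episodes)
kitchen_roles <- function() {
  c(
    "refrigerator", "rice_cooker", "kitchen_sink_faucet", "microwave",
    "cupboard"
  )
}
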