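# Personas: the behavioral parameters that drive the synthetic cohort.
# Defaults encode the group contrasts the analysis is designed to detect:
# gait-speed means at the two groups' printed values (1.023 vs 1.2091 km/h),
# lower kitchen-appliance coherence and higher late-night activity in the
# dementia group, and a higher probability of leaving appliances powered
# when going out.

#' Persona parameters for one simulated resident
#'
#' @param meal_cook_prob Length-3 probability vector (breakfast, lunch,
#'   dinner) that a mealtime window contains a cooking attempt.
#' @param appliance_coherence Probability in `[0, 1]` that each kitchen
#'   appliance joins a cooking episode (co-occurrence strength); incoherent
#'   scattered appliance uses grow as it falls.
#' @param med_adherence_prob Probability that a scheduled medication dose is
#'   taken.
#' @param med_time_jitter_min SD (minutes) of dose-time jitter.
#' @param night_activity_rate Expected activity bouts per hour in 00:00-05:00.
#' @param forget_appliance_on_prob Probability an outing leaves the TV or
#'   electric mat powered.
#' @param gait_speed_mean_kmh,gait_speed_sd_kmh Walking speed distribution
#'   (km/h) sampled by the lidar track.
#' @param task_duration_scale Multiplier (>= 1) on task durations.
#' @param ... Further named scheduling parameters (wake/sleep hours, outing,
#'   shower, laundry, TV and mat habits); see `default_personas()` for the
#'   full set and defaults.
#' @return A named list of class `persona_params`.
#' @export
persona_params <- function(meal_cook_prob = c(0.8, 0.6, 0.85),
                           appliance_coherence = 0.85,
                           med_adherence_prob = 0.9,
                           med_time_jitter_min = 15,
                           night_activity_rate = 0.25,
                           forget_appliance_on_prob = 0.05,
                           gait_speed_mean_kmh = 1.023,
                           gait_speed_sd_kmh = 0.35,
                           task_duration_scale = 1,
                           ...) {
  p <- c(
    list(
      meal_cook_prob = meal_cook_prob,
      appliance_coherence = appliance_coherence,
      med_adherence_prob = med_adherence_prob,
      med_time_jitter_min = med_time_jitter_min,
      night_activity_rate = night_activity_rate,
      forget_appliance_on_prob = forget_appliance_on_prob,
      gait_speed_mean_kmh = gait_speed_mean_kmh,
      gait_speed_sd_kmh = gait_speed_sd_kmh,
      task_duration_scale = task_duration_scale
    ),
    list(...)
  )
  defaults <- list(
    wake_hour = 6.5, sleep_hour = 22.5,
    outing_prob = 0.7, shower_prob = 0.6, washer_prob = 0.3,
    tv_morning_prob = 0.5, tv_night_prob = 0.05,
    mat_night_prob = 0.7, mat_day_prob = 0.05,
    dishes_prob = 0.8, vacuum_prob = 0.25,
    wander_walks_per_day = 3
  )
  p <- modifyList(defaults, p)
  probs <- c(
    p$meal_cook_prob, p$appliance_coherence, p$med_adherence_prob,
    p$forget_appliance_on_prob, p$outing_prob, p$shower_prob,
    p$washer_prob, p$tv_morning_prob, p$tv_night_prob, p$mat_night_prob,
    p$mat_day_prob, p$dishes_prob, p$vacuum_prob
  )
  if (any(probs < 0 | probs > 1)) stop_config("persona probabilities must lie in [0, 1]")
  if (length(p$meal_cook_prob) != 3) stop_config("meal_cook_prob must have length 3")
  if (p$gait_speed_mean_kmh <= 0) stop_config("gait_speed_mean_kmh must be > 0")
  if (p$task_duration_scale < 1) stop_config("task_duration_scale must be >= 1")
  if (p$night_activity_rate < 0) stop_config("night_activity_rate must be >= 0")
  structure(p, class = "persona_params")
}

#' Default group personas
#'
#' The two persona templates the synthetic cohort draws from. Group-level
#' contrasts: the dementia persona cooks less coherently, is more active at
#' night, adheres less reliably to medication schedules, more often leaves
#' appliances powered during outings, walks at the dementia group's printed
#' mean gait speed, and takes longer over tasks.
#'
#' @return Named list with elements `normal` and `dementia`.
#' @export
default_personas <- function() {
  list(
    normal = persona_params(
      meal_cook_prob = c(0.80, 0.60, 0.85),
      appliance_coherence = 0.85,
      med_adherence_prob = 0.92,
      med_time_jitter_min = 15,
      night_activity_rate = 0.25,
      forget_appliance_on_prob = 0.05,
      gait_speed_mean_kmh = 1.023,
      gait_speed_sd_kmh = 0.35,
      task_duration_scale = 1,
      wake_hour = 6.5, sleep_hour = 22.5,
      outing_prob = 0.7, shower_prob = 0.6, washer_prob = 0.3,
      tv_morning_prob = 0.5, tv_night_prob = 0.05,
      mat_night_prob = 0.7, mat_day_prob = 0.05,
      dishes_prob = 0.8, vacuum_prob = 0.25,
      wander_walks_per_day = 3
    ),
    dementia = persona_params(
      meal_cook_prob = c(0.55, 0.40, 0.60),
      appliance_coherence = 0.35,
      med_adherence_prob = 0.65,
      med_time_jitter_min = 45,
      night_activity_rate = 1.25,
      forget_appliance_on_prob = 0.45,
      gait_speed_mean_kmh = 1.2091,
      gait_speed_sd_kmh = 0.45,
      task_duration_scale = 1.5,
      wake_hour = 7, sleep_hour = 23.2,
      outing_prob = 0.5, shower_prob = 0.35, washer_prob = 0.15,
      tv_morning_prob = 0.4, tv_night_prob = 0.45,
      mat_night_prob = 0.7, mat_day_prob = 0.35,
      dishes_prob = 0.5, vacuum_prob = 0.12,
      wander_walks_per_day = 6
    )
  )
}

# Person-to-person variation around a group template. Keeps every draw inside
# the persona's validity ranges; the SDs give individuals overlapping habits
# so the groups are separable only in aggregate.
jitter_persona <- function(template, rng_noise = 1) {
  p <- template
  jp <- function(x, sd) clamp(x + rnorm(length(x), 0, sd * rng_noise), 0, 1)
  p$meal_cook_prob <- jp(p$meal_cook_prob, 0.08)
  p$appliance_coherence <- jp(p$appliance_coherence, 0.08)
  p$med_adherence_prob <- jp(p$med_adherence_prob, 0.06)
  p$med_time_jitter_min <- max(2, p$med_time_jitter_min * exp(rnorm(1, 0, 0.25)))
  p$night_activity_rate <- p$night_activity_rate * exp(rnorm(1, 0, 0.3))
  p$forget_appliance_on_prob <- jp(p$forget_appliance_on_prob, 0.08)
  p$gait_speed_mean_kmh <- max(0.3, p$gait_speed_mean_kmh + rnorm(1, 0, 0.06))
  p$task_duration_scale <- max(1, p$task_duration_scale + rnorm(1, 0, 0.1))
  p$outing_prob <- jp(p$outing_prob, 0.1)
  p$shower_prob <- jp(p$shower_prob, 0.1)
  p$washer_prob <- jp(p$washer_prob, 0.07)
  p$tv_night_prob <- jp(p$tv_night_prob, 0.07)
  p$mat_day_prob <- jp(p$mat_day_prob, 0.07)
  p$dishes_prob <- jp(p$dishes_prob, 0.08)
  p$wake_hour <- clamp(p$wake_hour + rnorm(1, 0, 0.4), 5, 9)
  p$sleep_hour <- clamp(p$sleep_hour + rnorm(1, 0, 0.4), 20.5, 23.8)
  p
}

#' Cohort configuration for the synthetic generator
#'
#' @param n_normal,n_dementia Group sizes (default 7 and 6, the reference
#'   cohort composition).
#' @param days Days of observation per person.
#' @param start_date First simulated calendar day (`YYYY-MM-DD`).
#' @param personas Group persona templates, as [default_personas()].
#' @param mmse Optional list with numeric vectors `normal` and `dementia`
#'   overriding the default MMSE assignments.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_normal = 7, n_dementia = 6, days = 14,
                          start_date = "2020-07-06",
                          personas = default_personas(), mmse = NULL) {
  if (n_normal < 1 || n_dementia < 1) stop_config("group sizes must be positive")
  if (days < 1) stop_config("days must be positive")
  structure(
    list(
      n_normal = n_normal, n_dementia = n_dementia, days = days,
      start_date = start_date, personas = personas, mmse = mmse
    ),
    class = "cohort_config"
  )
}

# Default cognitive profiles. The first seven normal / six dementia slots use
# the reference cohort's MMSE/CDR pattern (group means 27.5 and 17.6, one
# dementia participant with preserved MMSE 30 at CDR 0.5); larger cohorts
# extend by sampling around those means.
assign_cognition <- function(group, n, mmse_override = NULL) {
  if (group == "normal") {
    base_mmse <- c(26, 29, 25, 27, 26, 30, 30)
    mmse <- if (!is.null(mmse_override)) {
      mmse_override
    } else if (n <= length(base_mmse)) {
      base_mmse[seq_len(n)]
    } else {
      c(base_mmse, clamp(round(rnorm(n - 7, 27.5, 1.9)), 24, 30))
    }
    cdr <- rep(0, n)
  } else {
    base_mmse <- c(20, 13, 18, 30, 11, 14)
    base_cdr <- c(1, 1, 1, 0.5, 1, 1)
    if (!is.null(mmse_override)) {
      mmse <- mmse_override
      cdr <- ifelse(mmse >= 24, 0.5, 1)
    } else if (n <= length(base_mmse)) {
      mmse <- base_mmse[seq_len(n)]
      cdr <- base_cdr[seq_len(n)]
    } else {
      extra <- clamp(round(rnorm(n - 6, 17.6, 4.5)), 5, 30)
      mmse <- c(base_mmse, extra)
      cdr <- c(base_cdr, sample(c(0.5, 1), n - 6, replace = TRUE, prob = c(0.2, 0.8)))
    }
  }
  stopifnot(all(mmse >= 0 & mmse <= 30))
  tibble(mmse = as.integer(mmse[seq_len(n)]), cdr = cdr[seq_len(n)])
}
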